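# Internal helpers shared across modules.

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never clobber the
# session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

stop2 <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
    stop2(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stop2(sprintf("`%s` must be a probability in [0, 1]", name))
  }
  as.numeric(x)
}

check_prob_vector <- function(p, name, tol = 1e-9) {
  if (any(p < -tol) || abs(sum(p) - 1) > tol) {
    stop2(sprintf("`%s` must be a non-negative vector summing to 1 (got sum %.12g)",
                  name, sum(p)))
  }
  p / sum(p)
}

# Random fixed-length DNA strings over {A,C,G,T}.
random_dna <- function(n, width) {
  if (n == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Zero-padded ids like "cell_00042".
pad_ids <- function(prefix, n) {
  sprintf(paste0(prefix, "_%0", max(5, nchar(n)), "d"), seq_len(n))
}
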