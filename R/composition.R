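# Clone-level fate-composition summaries: clone x state count tables,
# restricted-vs-mixed fractions, exclusive fate classification, and
# UpSet-style intersection counts.

#' Clone-by-state count table
#'
#' @param clones Clone table with `clone_id` and the state column.
#' @param state_col Column holding state labels (default `"subtype"`).
#' @return Integer matrix clones x states; row sums equal clone sizes.
#' @export
fate_table <- function(clones, state_col = "subtype") {
  pr <- prep_states(clones, state_col)
  K <- max(pr$clone_idx)
  m <- state_count_matrix(pr$clone_idx, pr$state_idx, K, length(pr$states))
  dimnames(m) <- list(sort(unique(clones$clone_id)), pr$states)
  m
}

# presence (>= presence_min cells) of each named state group per clone
group_presence <- function(clones, groups, presence_min, state_col) {
  all_states <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_states)) {
    stop2("state groups overlap: ",
          paste(unique(all_states[duplicated(all_states)]), collapse = ", "))
  }
  ft <- fate_table(clones, state_col)
  pres <- vapply(groups, function(st) {
    st <- intersect(st, colnames(ft))
    if (!length(st)) return(rep(FALSE, nrow(ft)))
    rowSums(ft[, st, drop = FALSE]) >= presence_min
  }, logical(nrow(ft)))
  if (nrow(ft) == 1) pres <- matrix(pres, nrow = 1, dimnames = list(NULL, names(groups)))
  rownames(pres) <- rownames(ft)
  pres
}

#' Fractions of restricted versus mixed clones
#'
#' Among clones containing the anchor group (>= `presence_min` cells of any
#' anchor state), classifies each clone by which other groups it also
#' contains: `"<anchor> only"` when no partner group is present, otherwise
#' `"<anchor>+<partners> mix"`. The categories are mutually exclusive and
#' exhaustive over eligible clones, so the fractions sum to 1. This is the
#' "astrocyte-only versus excitatory-neuron + astrocyte mix" style of
#' summary.
#'
#' @param clones Clone table.
#' @param groups Named list of disjoint state-label vectors; the first (or
#'   `anchor`) defines eligibility.
#' @param anchor Name of the anchoring group (default the first of
#'   `groups`).
#' @param presence_min Cells required for a group to count as present
#'   (default 1).
#' @param state_col State column name.
#' @return Data frame `category`, `n`, `fraction`; attribute `n_eligible`.
#' @examples
#' tb <- data.frame(cell_id = paste0("c", 1:6),
#'                  clone_id = c(1, 1, 2, 2, 3, 3),
#'                  subtype = c("Ast", "Ast", "Ast", "Neuron", "Neuron", "Neuron"))
#' clone_category_fractions(tb, groups = list(Ast = "Ast", Neuron = "Neuron"))
#' @export
clone_category_fractions <- function(clones, groups, anchor = names(groups)[1],
                                     presence_min = 1, state_col = "subtype") {
  presence_min <- check_count(presence_min, "presence_min")
  if (!anchor %in% names(groups)) stop2("`anchor` must name one of `groups`")
  pres <- group_presence(clones, groups, presence_min, state_col)
  eligible <- pres[, anchor]
  partners <- setdiff(colnames(pres), anchor)
  cat_of <- apply(pres[eligible, , drop = FALSE], 1, function(p) {
    with_p <- partners[p[partners]]
    if (!length(with_p)) paste(anchor, "only")
    else paste0(anchor, "+", paste(sort(with_p), collapse = "+"), " mix")
  })
  lev <- c(paste(anchor, "only"),
           sort(unique(cat_of[cat_of != paste(anchor, "only")])))
  cnt <- table(factor(cat_of, levels = lev))
  out <- data.frame(category = names(cnt), n = as.integer(cnt),
                    fraction = as.numeric(cnt) / max(sum(cnt), 1),
                    stringsAsFactors = FALSE)
  attr(out, "n_eligible") <- sum(eligible)
  out
}

#' Intersection (UpSet) counts of clone contents
#'
#' For each observed combination of states present in a clone (presence =
#' at least `presence_min` cells), the number of clones with exactly that
#' combination. Clones containing none of the queried states are excluded;
#' the combination counts sum to the number of eligible clones.
#'
#' @param clones Clone table.
#' @param states Character vector of state labels to intersect.
#' @param presence_min Cells required for presence (default 1).
#' @param state_col State column name.
#' @return Data frame `set` (states joined by `"&"`), `degree`, `n`,
#'   ordered by decreasing count; attribute `n_eligible`.
#' @export
upset_intersections <- function(clones, states, presence_min = 1,
                                state_col = "subtype") {
  presence_min <- check_count(presence_min, "presence_min")
  if (!length(states)) stop2("need at least one state")
  if (!nrow(clones)) {
    out <- data.frame(set = character(0), degree = integer(0), n = integer(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_eligible") <- 0L
    return(out)
  }
  groups <- as.list(states)
  names(groups) <- states
  pres <- group_presence(clones, groups, presence_min, state_col)
  nonempty <- rowSums(pres) > 0
  sets <- apply(pres[nonempty, , drop = FALSE], 1, function(p) {
    paste(states[p], collapse = "&")
  })
  cnt <- sort(table(sets), decreasing = TRUE)
  out <- data.frame(set = names(cnt),
                    degree = lengths(strsplit(names(cnt), "&", fixed = TRUE)),
                    n = as.integer(cnt), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_eligible") <- sum(nonempty)
  out
}

#' Default precedence rules for exclusive fate classification
#'
#' Ordered containment rules matched against clone contents, first match
#' wins: a clone containing any Olig2-lineage astrocyte is "olig2_astro",
#' else one containing any S100a11-lineage astrocyte is "s100a11_astro",
#' else one containing any neuron is "neuron"; clones matching no rule
#' (progenitors only) fall back to "self_renew".
#'
#' @return Named list of state-label vectors, in precedence order.
#' @export
default_fate_rules <- function() {
  list(olig2_astro = "Astro_Olig2",
       s100a11_astro = "Astro_S100a11",
       neuron = "Neuron")
}

#' Exclusive fate classification of clones
#'
#' Assigns each clone exactly one fate category via ordered precedence
#' rules: the first rule whose states are present in the clone (at least
#' `presence_min` cells summed over the rule's states) gives the category;
#' unmatched clones get `fallback`. Categories therefore sum to 100% of
#' classified clones.
#'
#' @param clones Clone table.
#' @param rules Ordered named list of state vectors (see
#'   [default_fate_rules()]).
#' @param fallback Category for clones matching no rule.
#' @param presence_min Cells required for a rule to fire (default 1).
#' @param state_col State column name.
#' @return Data frame `clone_id`, `category`.
#' @export
classify_clone_fates <- function(clones, rules = default_fate_rules(),
                                 fallback = "self_renew", presence_min = 1,
                                 state_col = "subtype") {
  presence_min <- check_count(presence_min, "presence_min")
  ft <- fate_table(clones, state_col)
  category <- rep(fallback, nrow(ft))
  unassigned <- rep(TRUE, nrow(ft))
  for (nm in names(rules)) {
    st <- intersect(rules[[nm]], colnames(ft))
    hit <- if (length(st)) {
      rowSums(ft[, st, drop = FALSE]) >= presence_min
    } else rep(FALSE, nrow(ft))
    category[unassigned & hit] <- nm
    unassigned <- unassigned & !hit
  }
  data.frame(clone_id = rownames(ft), category = category,
             stringsAsFactors = FALSE)
}

#' Exclusive fate fractions of clones containing a focal state
#'
#' Restricts to clones containing at least `eligible_min` cells of the
#' focal state (e.g. a progenitor subtype), classifies them with
#' [classify_clone_fates()], and reports category fractions — the
#' "fraction of progenitor clones within each lineage" style of summary.
#'
#' @param clones Clone table.
#' @param focal_state State defining clone eligibility.
#' @param eligible_min Cells of the focal state required (default 1).
#' @inheritParams classify_clone_fates
#' @return Data frame `category`, `n`, `fraction`; attribute `n_eligible`.
#' @export
exclusive_fate_fractions <- function(clones, focal_state,
                                     rules = default_fate_rules(),
                                     fallback = "self_renew",
                                     presence_min = 1, eligible_min = 1,
                                     state_col = "subtype") {
  eligible_min <- check_count(eligible_min, "eligible_min")
  ft <- fate_table(clones, state_col)
  if (!focal_state %in% colnames(ft)) {
    stop2(sprintf("focal state '%s' absent; known states: %s", focal_state,
                  paste(colnames(ft), collapse = ", ")))
  }
  keep_ids <- rownames(ft)[ft[, focal_state] >= eligible_min]
  sub <- clones[as.character(clones$clone_id) %in% keep_ids, , drop = FALSE]
  if (!nrow(sub)) stop2("no eligible clones for focal state ", focal_state)
  cls <- classify_clone_fates(sub, rules, fallback, presence_min, state_col)
  lev <- unique(c(names(rules), fallback))
  cnt <- table(factor(cls$category, levels = lev))
  out <- data.frame(category = names(cnt), n = as.integer(cnt),
                    fraction = as.numeric(cnt) / sum(cnt),
                    stringsAsFactors = FALSE)
  attr(out, "n_eligible") <- length(keep_ids)
  out
}
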