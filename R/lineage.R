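#' Count descendants of each ancestor at a horizon
#'
#' Walks a parent-child division event table and counts, for each ancestor,
#' the cells of its subtree alive at the horizon (cells that have been born
#' by then and have not yet divided). The table must form a forest: a
#' validation error naming the offending rows is raised if any cell has two
#' parents or appears in a cycle.
#'
#' @param events tibble with columns `parent_id`, `child_id`, `time_days`
#'   (two child rows per division).
#' @param ancestors tibble with columns `ancestor_id` and `signaling_class`
#'   (or a character vector of ancestor ids, in which case the class is
#'   `NA`).
#' @param horizon_days counting horizon; divisions after it are ignored.
#' @return tibble of lineage records: `ancestor_id`, `signaling_class`,
#'   `lineage_size`.
#' @export
#' @examples
#' ev <- tibble::tibble(parent_id = c("a", "a"), child_id = c("a.1", "a.2"),
#'                      time_days = 1)
#' count_descendants(ev, "a", horizon_days = 7)
count_descendants <- function(events, ancestors, horizon_days) {
  check_number(horizon_days, "horizon_days", lower = 0)
  events <- tibble::as_tibble(events)
  need <- c("parent_id", "child_id", "time_days")
  if (!all(need %in% names(events))) {
    stop_param("`events` must have columns parent_id, child_id, time_days")
  }
  if (is.data.frame(ancestors)) {
    anc_ids <- as.character(ancestors$ancestor_id)
    classes <- as.character(ancestors$signaling_class)
  } else {
    anc_ids <- as.character(ancestors)
    classes <- rep(NA_character_, length(anc_ids))
  }
  validate_forest(events, anc_ids)
  ev <- events[events$time_days <= horizon_days, , drop = FALSE]
  child <- as.character(ev$child_id)
  parent <- as.character(ev$parent_id)
  divided <- unique(parent)
  # leaves alive at horizon: born by horizon (all rows pass the filter) and
  # not among the divided parents
  leaves <- setdiff(unique(c(anc_ids, child)), divided)
  # climb all chains simultaneously (hashed match, one level per pass)
  roots <- leaves
  repeat {
    i <- match(roots, child)
    hit <- !is.na(i)
    if (!any(hit)) break
    roots[hit] <- parent[i[hit]]
  }
  counts <- table(factor(roots, levels = anc_ids))
  tibble::tibble(
    ancestor_id = anc_ids,
    signaling_class = classes,
    lineage_size = as.integer(counts)
  )
}

validate_forest <- function(events, anc_ids) {
  child <- as.character(events$child_id)
  dup <- unique(child[duplicated(child)])
  if (length(dup) > 0) {
    abort(paste0("event table is not a forest: cell(s) with two parents: ",
                 paste(utils::head(dup, 5), collapse = ", ")))
  }
  if (any(child %in% anc_ids)) {
    abort(paste0("event table is not a forest: ancestor appears as a child: ",
                 paste(utils::head(intersect(child, anc_ids), 5), collapse = ", ")))
  }
  # cycle check: climb every chain in lockstep; any chain still unresolved
  # after as many levels as there are edges must be cyclic
  parent <- as.character(events$parent_id)
  cur <- child
  for (step in seq_len(length(child) + 1L)) {
    i <- match(cur, child)
    hit <- !is.na(i)
    if (!any(hit)) return(invisible(TRUE))
    cur[hit] <- parent[i[hit]]
  }
  bad <- child[!is.na(match(cur, child))]
  abort(paste0("event table contains a cycle involving: ",
               paste(utils::head(unique(bad), 5), collapse = ", ")))
}

#' Compare lineage sizes between signaling classes
#'
#' Pools lineage records into a reactivating group (`signaling_class ==
#' "recovering"`) and a non-reactivating group (everything else) and tests
#' whether the two groups have identical lineage sizes with a two-sided
#' Wilcoxon rank-sum test and a Welch two-tailed t-test. The rank-sum test
#' uses the normal approximation with mid-ranks and tie correction; when
#' the combined sample size is at most 20 an exact permutation p-value
#' (full enumeration of group assignments) is used instead.
#'
#' @param records lineage-record tibble (see [count_descendants()]).
#' @param drop_dead drop records with `lineage_size == 0` (dead/detached
#'   ancestors) before testing; default keeps them.
#' @return a one-row tibble: group means and sizes, `p_ranksum`,
#'   `p_ttest`, and the rank-sum method used.
#' @export
compare_groups <- function(records, drop_dead = FALSE) {
  records <- tibble::as_tibble(records)
  if (drop_dead) records <- records[records$lineage_size > 0, , drop = FALSE]
  rec <- records$lineage_size[records$signaling_class == "recovering"]
  oth <- records$lineage_size[records$signaling_class != "recovering"]
  if (length(rec) < 2 || length(oth) < 2) {
    abort("each pooled group needs at least 2 records")
  }
  n <- length(rec) + length(oth)
  if (n <= 20) {
    p_rank <- exact_ranksum_p(rec, oth)
    method <- "exact permutation"
  } else {
    p_rank <- suppressWarnings(
      wilcox.test(rec, oth, correct = FALSE, exact = FALSE)$p.value
    )
    method <- "normal approximation"
  }
  p_t <- if (sd(rec) == 0 && sd(oth) == 0) {
    if (mean(rec) == mean(oth)) 1 else 0
  } else {
    t.test(rec, oth, var.equal = FALSE)$p.value
  }
  tibble::tibble(
    mean_recovering = mean(rec),
    mean_non_recovering = mean(oth),
    n_recovering = length(rec),
    n_non_recovering = length(oth),
    p_ranksum = p_rank,
    p_ttest = p_t,
    ranksum_method = method
  )
}

# Two-sided exact permutation p-value for the rank-sum statistic,
# enumerating every assignment of the pooled sample into the two groups.
exact_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n_a <- length(a)
  obs <- sum(r[seq_len(n_a)])
  combos <- utils::combn(length(pooled), n_a)
  sums <- colSums(matrix(r[combos], nrow = n_a))
  expected <- n_a * (length(pooled) + 1) / 2
  mean(abs(sums - expected) >= abs(obs - expected) - 1e-9)
}
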