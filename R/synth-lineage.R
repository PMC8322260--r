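#' Simulate class-dependent cell lineages over a multi-day horizon
#'
#' Runs a stochastic division process for each ancestor according to its
#' signaling class and the chosen division model (see [growth_params()]).
#' Model parameters are calibrated analytically before simulation so that
#' the expected lineage size at the horizon equals the class target means.
#'
#' Under `"delayed-arrest"`, every cell completes a further in-progress
#' division with probability `p0` (recorded at event time 0: mitoses already
#' under way when the drug is added complete at the start of observation);
#' cells that stop are arrested if their ancestor is non-reactivating, while
#' cells of reactivating ancestors divide as a Poisson (Yule) process at
#' rate `lambda` for the rest of the horizon. The flat-class mean is
#' `(1 - p0) / (1 - 2 p0)` and the recovering-class mean multiplies that by
#' `exp(lambda * horizon)`; `p0` and `lambda` are solved from the targets
#' (a recovering target below the flat target is uncalibratable and raises
#' a parameter error). Under `"rate-switch"` each class is a pure-birth
#' process with rate `log(target) / horizon`.
#'
#' @param labels character vector of ancestor classes; `"recovering"` means
#'   the reactivating class, anything else is treated as non-reactivating.
#'   A tibble with columns `cell_id` and `class` is also accepted.
#' @param gparams a [growth_params()] object.
#' @param seed integer seed; identical seeds give identical tables.
#' @return list with
#'   \describe{
#'     \item{records}{tibble: `ancestor_id`, `signaling_class`,
#'       `lineage_size` (cells alive at horizon, ancestor counted).}
#'     \item{events}{tibble of divisions: `parent_id`, `child_id`,
#'       `time_days` (two child rows per division; the parent ceases to
#'       exist when it divides).}
#'   }
#' @export
#' @examples
#' lin <- simulate_lineages(c("recovering", "flat"), growth_params(), seed = 7)
#' lin$records
simulate_lineages <- function(labels, gparams = growth_params(), seed = NULL) {
  if (is.data.frame(labels)) {
    ids <- as.character(labels$cell_id)
    labels <- as.character(labels$class)
  } else {
    labels <- as.character(labels)
    ids <- sprintf("anc_%04d", seq_along(labels))
  }
  if (length(labels) == 0) stop_param("`labels` must be nonempty")
  if (!inherits(gparams, "growth_params")) {
    stop_param("`gparams` must be created with growth_params()")
  }
  cal <- calibrate_division_model(gparams)
  with_seed(seed, {
    res <- purrr::map2(ids, labels, function(id, cls) {
      simulate_one_lineage(id, identical(cls, "recovering"), gparams, cal)
    })
    records <- tibble::tibble(
      ancestor_id = ids,
      signaling_class = labels,
      lineage_size = purrr::map_int(res, "size")
    )
    events <- tibble::tibble(
      parent_id = unlist(purrr::map(res, "parent")) %||% character(),
      child_id = unlist(purrr::map(res, "child")) %||% character(),
      time_days = unlist(purrr::map(res, "time")) %||% numeric()
    )
    list(records = records, events = events)
  })
}

# Solve the division-model parameters from the target class means.
calibrate_division_model <- function(gparams) {
  T <- gparams$horizon_days
  m_flat <- gparams$mean_lineage_flat
  m_rec <- gparams$mean_lineage_recovering
  if (gparams$division_model == "rate-switch") {
    if (T <= 0) return(list(rate_flat = 0, rate_rec = 0))
    return(list(rate_flat = log(m_flat) / T, rate_rec = log(m_rec) / T))
  }
  # delayed-arrest: E[size | flat] = (1 - p0)/(1 - 2 p0)
  p0 <- (m_flat - 1) / (2 * m_flat - 1)
  if (p0 < 0 || p0 >= 0.5) {
    stop_param("uncalibratable division model: mean_lineage_flat = ", m_flat)
  }
  if (m_rec < m_flat) {
    stop_param("uncalibratable division model: mean_lineage_recovering (",
               m_rec, ") below mean_lineage_flat (", m_flat, ")")
  }
  lambda <- if (T > 0) log(m_rec / m_flat) / T else 0
  list(p0 = p0, lambda = lambda)
}

simulate_one_lineage <- function(ancestor_id, recovering, gparams, cal) {
  T <- gparams$horizon_days
  ev_parent <- character()
  ev_child <- character()
  ev_time <- numeric()
  next_id <- 1L
  if (T <= 0) {
    return(list(size = 1L, parent = ev_parent, child = ev_child,
                time = ev_time))
  }
  divide <- function(parent, time) {
    kids <- c(sprintf("%s.%d", ancestor_id, next_id),
              sprintf("%s.%d", ancestor_id, next_id + 1L))
    next_id <<- next_id + 2L
    ev_parent[length(ev_parent) + 1:2] <<- parent
    ev_child[length(ev_child) + 1:2] <<- kids
    ev_time[length(ev_time) + 1:2] <<- time
    kids
  }
  if (gparams$division_model == "delayed-arrest") {
    # residual-division phase at t = 0: each cell divides once more w.p. p0
    pending <- ancestor_id
    alive <- character()
    while (length(pending) > 0) {
      cell <- pending[[1]]
      pending <- pending[-1]
      if (runif(1) < cal$p0) {
        pending <- c(pending, divide(cell, 0))
      } else {
        alive <- c(alive, cell)
      }
    }
    if (recovering && cal$lambda > 0) {
      # Yule phase: every live cell divides at rate lambda until the horizon
      queue_id <- alive
      queue_t <- rep(0, length(alive))
      alive <- character()
      while (length(queue_id) > 0) {
        cell <- queue_id[[1]]; t0 <- queue_t[[1]]
        queue_id <- queue_id[-1]; queue_t <- queue_t[-1]
        t_div <- t0 + rexp(1, cal$lambda)
        if (t_div > T) {
          alive <- c(alive, cell)
        } else {
          kids <- divide(cell, t_div)
          queue_id <- c(queue_id, kids)
          queue_t <- c(queue_t, t_div, t_div)
        }
      }
    }
    size <- length(alive)
  } else {
    rate <- if (recovering) cal$rate_rec else cal$rate_flat
    alive <- character()
    queue_id <- ancestor_id
    queue_t <- 0
    while (length(queue_id) > 0) {
      cell <- queue_id[[1]]; t0 <- queue_t[[1]]
      queue_id <- queue_id[-1]; queue_t <- queue_t[-1]
      t_div <- if (rate > 0) t0 + rexp(1, rate) else Inf
      if (t_div > T) {
        alive <- c(alive, cell)
      } else {
        kids <- divide(cell, t_div)
        queue_id <- c(queue_id, kids)
        queue_t <- c(queue_t, t_div, t_div)
      }
    }
    size <- length(alive)
  }
  list(size = as.integer(size), parent = ev_parent, child = ev_child,
       time = ev_time)
}
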