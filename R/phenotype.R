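# Whole-plant outcome metrics after a hypoxia episode.

#' Seedling injury counts
#'
#' @param healthy,damaged,dead Non-negative integer counts of seedlings per
#'   injury category after recovery.
#' @return An object of class `injury_counts`.
#' @export
injury_counts <- function(healthy, damaged, dead) {
  v <- c(healthy = healthy, damaged = damaged, dead = dead)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    stop("counts must be non-negative integers")
  if (sum(v) == 0) stop("total count must be > 0")
  structure(as.list(v), class = "injury_counts")
}

#' Weighted hypoxia survival score
#'
#' Seedlings are categorized after recovery as healthy (five points), damaged
#' (three points) or dead (one point); the score is the count-weighted mean,
#' \deqn{(5 h + 3 d + 1 x) / (h + d + x) \in [1, 5].}
#'
#' @param counts An [injury_counts()], or the healthy count if `damaged` and
#'   `dead` are given.
#' @param damaged,dead Optional counts when `counts` is a plain number.
#' @return Score in \[1, 5\].
#' @examples
#' survival_score(injury_counts(2, 1, 1))  # 3.5
#' survival_score(4, 0, 0)                 # 5
#' @export
survival_score <- function(counts, damaged = NULL, dead = NULL) {
  if (!inherits(counts, "injury_counts"))
    counts <- injury_counts(counts, damaged, dead)
  total <- counts$healthy + counts$damaged + counts$dead
  (5 * counts$healthy + 3 * counts$damaged + 1 * counts$dead) / total
}

#' Fraction of seedlings resuming root growth
#'
#' @param resumed Number of seedlings that resumed primary root growth after
#'   the hypoxia episode.
#' @param total Total number of seedlings (> 0, >= `resumed`).
#' @return Percentage `100 * resumed / total`.
#' @examples
#' resumed_fraction(17, 45)  # 37.8 percent
#' @export
resumed_fraction <- function(resumed, total) {
  if (!is.finite(resumed) || !is.finite(total) || total <= 0 ||
      resumed < 0 || resumed > total)
    stop("need 0 <= resumed <= total with total > 0")
  100 * resumed / total
}
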