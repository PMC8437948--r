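#' Severity group labels
#' @return character vector of the five severity groups, mildest first.
#' @export
severity_levels <- function() {
  c("healthy", "mild", "moderate", "severe", "very_severe")
}

#' Map erythema and scaling scores to a severity group
#'
#' Each indicator is graded 0-4; the group is banded on the score sum:
#' healthy (0), mild (1-2), moderate (3-4), severe (5-6), very severe
#' (7-8).
#'
#' @param erythema_score,scale_score integer scores in 0..4 (vectorised).
#' @return tibble with columns `erythema`, `scale`, `score_sum`, `group`
#'   (factor over [severity_levels()]).
#' @export
severity_group <- function(erythema_score, scale_score) {
  if (any(!erythema_score %in% 0:4) || any(!scale_score %in% 0:4))
    stop("scores must be integers in 0..4", call. = FALSE)
  s <- erythema_score + scale_score
  grp <- cut(s, breaks = c(-0.5, 0.5, 2.5, 4.5, 6.5, 8.5),
             labels = severity_levels())
  tibble::tibble(erythema = as.integer(erythema_score),
                 scale = as.integer(scale_score),
                 score_sum = as.integer(s),
                 group = factor(as.character(grp), levels = severity_levels()))
}

#' PASI score from per-region indicator grades
#'
#' The Psoriasis Area and Severity Index aggregates erythema (E),
#' thickness (T) and scaling (S), each graded 0-4, and an area grade A
#' (0-6) over four body regions with fixed weights:
#' \deqn{0.1 (E+T+S)_h A_h + 0.2 (E+T+S)_u A_u + 0.3 (E+T+S)_t A_t +
#'       0.4 (E+T+S)_l A_l}
#' for head, upper extremities, trunk and lower extremities.  Range
#' 0-72.
#'
#' @param scores data frame with columns `region` (subset of `"head"`,
#'   `"upper"`, `"trunk"`, `"lower"`), `E`, `T`, `S` (0-4) and `A` (0-6).
#'   Regions not listed contribute 0.
#' @return single numeric PASI score.
#' @export
pasi_score <- function(scores) {
  scores <- as.data.frame(scores)
  need <- c("region", "E", "T", "S", "A")
  if (!all(need %in% names(scores)))
    stop("`scores` needs columns region, E, T, S, A", call. = FALSE)
  wt <- c(head = 0.1, upper = 0.2, trunk = 0.3, lower = 0.4)
  if (!all(scores$region %in% names(wt)))
    stop("unknown region; use head/upper/trunk/lower", call. = FALSE)
  if (anyDuplicated(scores$region))
    stop("duplicate region rows", call. = FALSE)
  for (v in c("E", "T", "S"))
    if (any(!scores[[v]] %in% 0:4))
      stop(v, " grades must be integers in 0..4", call. = FALSE)
  if (any(!scores$A %in% 0:6))
    stop("A grades must be integers in 0..6", call. = FALSE)
  sum(wt[scores$region] * (scores$E + scores$T + scores$S) * scores$A)
}
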