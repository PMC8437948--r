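#' @title Segmentation similarity metrics
#'
#' @description Five indicators comparing a predicted binary mask with a
#' ground-truth mask: Dice coefficient, global consistency error (GCE),
#' variation of information (VoI, bits), Hausdorff distance (pixels) and
#' Rand index.  GCE, VoI and RI treat each mask as the two-region
#' partition \{foreground, background\} of the pixel grid.  For identical
#' masks the report is (1, 0, 0, 0, 1); lower is better for GCE, VoI and
#' HD, higher for Dice and RI.
#'
#' @name seg_similarity
NULL

mask_pair_counts <- function(a, b) {
  assert_mask(a, "a"); assert_mask(b, "b"); assert_same_shape(a, b)
  c(n11 = sum(a & b), n10 = sum(a & !b), n01 = sum(!a & b), n00 = sum(!a & !b))
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b logical matrices of identical shape.
#' @return value in `[0, 1]`.
#' @export
dice <- function(a, b) {
  ct <- mask_pair_counts(a, b)
  denom <- 2 * ct[["n11"]] + ct[["n10"]] + ct[["n01"]]
  if (denom == 0) return(1)
  2 * ct[["n11"]] / denom
}

#' Global consistency error
#'
#' Martin's GCE between the two-region partitions induced by the masks:
#' the minimum over directions of the summed local refinement error
#' `|R(a,x) \ R(b,x)| / |R(a,x)|`, divided by the pixel count.
#'
#' @inheritParams dice
#' @return value in `[0, 1]`; 0 when one partition refines the other.
#' @export
gce <- function(a, b) {
  ct <- mask_pair_counts(a, b)
  n <- sum(ct)
  na1 <- ct[["n11"]] + ct[["n10"]]; na0 <- ct[["n01"]] + ct[["n00"]]
  nb1 <- ct[["n11"]] + ct[["n01"]]; nb0 <- ct[["n10"]] + ct[["n00"]]
  # summed refinement error in each direction, from the contingency table
  e_ab <- 0
  if (na1 > 0) e_ab <- e_ab + 2 * ct[["n11"]] * ct[["n10"]] / na1
  if (na0 > 0) e_ab <- e_ab + 2 * ct[["n01"]] * ct[["n00"]] / na0
  e_ba <- 0
  if (nb1 > 0) e_ba <- e_ba + 2 * ct[["n11"]] * ct[["n01"]] / nb1
  if (nb0 > 0) e_ba <- e_ba + 2 * ct[["n10"]] * ct[["n00"]] / nb0
  min(e_ab, e_ba) / n
}

#' Variation of information (bits)
#'
#' `VI = H(A) + H(B) - 2 I(A; B)` with base-2 logarithms; 0 for identical
#' partitions.
#'
#' @inheritParams dice
#' @return non-negative value in bits.
#' @export
voi <- function(a, b) {
  ct <- mask_pair_counts(a, b)
  n <- sum(ct)
  pj <- matrix(ct[c("n11", "n10", "n01", "n00")], 2, 2) / n  # rows: a, cols: b
  pa <- rowSums(pj); pb <- colSums(pj)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  mi <- 0
  for (i in 1:2) for (j in 1:2) if (pj[i, j] > 0)
    mi <- mi + pj[i, j] * log2(pj[i, j] / (pa[i] * pb[j]))
  max(0, ent(pa) + ent(pb) - 2 * mi)
}

#' Hausdorff distance (pixels)
#'
#' Symmetric Hausdorff distance between the foreground point sets under
#' Euclidean pixel-centre distance.  Undefined (error) when either mask
#' is empty.
#'
#' @inheritParams dice
#' @return non-negative distance in pixels.
#' @export
hausdorff <- function(a, b) {
  assert_mask(a, "a"); assert_mask(b, "b"); assert_same_shape(a, b)
  if (!any(a) || !any(b))
    stop("HD undefined for empty set", call. = FALSE)
  ia <- which(a, arr.ind = TRUE); ib <- which(b, arr.ind = TRUE)
  hausdorff_cpp(as.numeric(ia[, 1]), as.numeric(ia[, 2]),
                as.numeric(ib[, 1]), as.numeric(ib[, 2]))
}

#' Rand index
#'
#' Fraction of unordered pixel pairs on which the two induced two-region
#' partitions agree (same-region vs different-region), via the
#' contingency-table closed form.
#'
#' @inheritParams dice
#' @return value in `[0, 1]`; label-swap invariant.
#' @export
rand_index <- function(a, b) {
  ct <- mask_pair_counts(a, b)
  n <- sum(ct)
  if (n < 2) stop("Rand index needs at least two pixels", call. = FALSE)
  ch2 <- function(x) x * (x - 1) / 2
  sum_nij2 <- sum(ch2(ct))
  sum_a2 <- ch2(ct[["n11"]] + ct[["n10"]]) + ch2(ct[["n01"]] + ct[["n00"]])
  sum_b2 <- ch2(ct[["n11"]] + ct[["n01"]]) + ch2(ct[["n10"]] + ct[["n00"]])
  tot <- ch2(n)
  (tot + 2 * sum_nij2 - sum_a2 - sum_b2) / tot
}

#' Five-metric similarity report
#'
#' @param pred predicted mask (logical matrix).
#' @param gt ground-truth mask of the same shape.
#' @return object of class `similarity_report`: named list with `dice`,
#'   `gce`, `voi`, `hd`, `ri`.  `hd` is `NA` when either mask is empty
#'   (distance to an empty set is undefined).
#' @export
evaluate_segmentation <- function(pred, gt) {
  hd <- if (any(pred) && any(gt)) hausdorff(pred, gt) else NA_real_
  structure(list(dice = dice(pred, gt), gce = gce(pred, gt),
                 voi = voi(pred, gt), hd = hd, ri = rand_index(pred, gt)),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("Segmentation similarity (higher is better: DICE, RI; lower: GCE, VoI, HD)\n")
  cat(sprintf("  DICE %.4f | GCE %.4f | VoI %.4f bits | HD %s px | RI %.4f\n",
              x$dice, x$gce, x$voi,
              ifelse(is.na(x$hd), "NA", sprintf("%.2f", x$hd)), x$ri))
  invisible(x)
}
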