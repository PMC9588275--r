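#' Slice-paired batch sampler
#'
#' Draws training pairs (one low-dose slice, one high-dose slice) from two
#' unpaired cohorts. Subjects are chosen uniformly at random from each
#' cohort. In slice-paired mode the two slices share the same normalised
#' slice position: the low slice index is drawn uniformly, and the high
#' slice is the one at the same relative position after length
#' normalisation (ties at half-integers round down, so "first pairs with
#' first" holds for equal-length scans). In unpaired mode (the ablation)
#' both slice indices are drawn independently. The emitted sequence is
#' deterministic for a fixed seed.
#'
#' @param low_cohort,high_cohort lists of [ct_volume()] objects.
#' @param n_batches number of pairs to draw.
#' @param paired logical; `TRUE` for the slice-paired strategy.
#' @param seed RNG seed.
#' @return A data frame with one row per pair: subject/slice indices and
#'   normalised slice positions for both domains.
#' @export
slice_paired_batches <- function(low_cohort, high_cohort, n_batches,
                                 paired = TRUE, seed = 1L) {
  if (length(low_cohort) == 0L || length(high_cohort) == 0L) {
    stopf("both cohorts must be non-empty")
  }
  nl <- vapply(low_cohort, n_slices, integer(1))
  nh <- vapply(high_cohort, n_slices, integer(1))
  with_seed(seed, {
    ls <- sample.int(length(low_cohort), n_batches, replace = TRUE)
    hs <- sample.int(length(high_cohort), n_batches, replace = TRUE)
    li <- vapply(ls, function(s) sample.int(nl[s], 1L), integer(1))
    lpos <- ifelse(nl[ls] > 1L, (li - 1) / (nl[ls] - 1), 0)
    if (paired) {
      # same normalised position, half-integers rounded down
      hi <- as.integer(ceiling(lpos * (nh[hs] - 1L) - 0.5) + 1L)
      hi <- pmin(pmax(hi, 1L), nh[hs])
    } else {
      hi <- vapply(hs, function(s) sample.int(nh[s], 1L), integer(1))
    }
    hpos <- ifelse(nh[hs] > 1L, (hi - 1) / (nh[hs] - 1), 0)
    data.frame(low_subject = ls, low_slice = li, low_pos = lpos,
               high_subject = hs, high_slice = hi, high_pos = hpos)
  })
}
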