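#' Seeded train/test split
#'
#' Partitions samples into training and testing sets by a seeded uniform
#' random permutation; the test set size is `round(test_fraction * N)`
#' (18 of 89 at the default fraction). The default seed of 20 follows the
#' study's random-state convention, but the permutation algorithm is this
#' package's own, so the membership is not identical to any other
#' implementation's split.
#'
#' @param x a [SpectralDataset-class], or a single integer sample count N.
#' @param test_fraction held-out proportion in (0, 1); default 0.2.
#' @param seed integer RNG seed; default 20.
#' @return A [SplitSpec-class].
#' @examples
#' sp <- splitDataset(89)
#' length(sp@test_indices)  # 18
#' @export
splitDataset <- function(x, test_fraction = 0.2, seed = 20) {
  n <- if (is(x, "SpectralDataset")) ncol(x) else as.integer(x)
  if (n < 5L) stop("need at least 5 samples to split")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly between 0 and 1")
  n_test <- as.integer(round(test_fraction * n))
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  new("SplitSpec", test_fraction = test_fraction, seed = as.numeric(seed),
      train_indices = sort(perm[seq_len(n - n_test) + n_test]),
      test_indices = sort(perm[seq_len(n_test)]))
}
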