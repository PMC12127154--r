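#' Deterministic train/validation/test split
#'
#' Randomly partitions `0:(n_records-1)` into train/val/test index lists at
#' the requested proportions (default 8:1:1). Subset sizes are fixed by the
#' largest-remainder rule, so each is within one record of `n * ratio`; the
#' assignment is a seeded permutation, identical for identical inputs.
#'
#' @param n_records number of records (>= 3).
#' @param ratios length-3 positive proportions summing to 1 (within 1e-9).
#' @param seed integer seed.
#' @return a `dataset_split`: list with 0-based integer vectors `train`,
#'   `val`, `test` and the `seed`.
#' @examples
#' s <- split_dataset(100, c(0.8, 0.1, 0.1), seed = 1)
#' lengths(s[c("train", "val", "test")])
#' @export
split_dataset <- function(n_records, ratios = c(0.8, 0.1, 0.1), seed = 1) {
  stop_if_not_scalar_num(n_records, "n_records", lo = 3)
  if (length(ratios) != 3L || any(ratios <= 0))
    stop("`ratios` must be three positive proportions", call. = FALSE)
  if (abs(sum(ratios) - 1) > 1e-9)
    stop("`ratios` must sum to 1 (got ", format(sum(ratios), digits = 12), ")",
         call. = FALSE)
  n <- as.integer(n_records)
  sizes <- floor(n * ratios)
  rem <- n - sum(sizes)
  if (rem > 0) {                        # largest-remainder apportionment
    frac <- n * ratios - sizes
    give <- order(frac, decreasing = TRUE)[seq_len(rem)]
    sizes[give] <- sizes[give] + 1L
  }
  perm <- with_seed(seed, sample.int(n)) - 1L
  structure(
    list(train = sort(perm[seq_len(sizes[1L])]),
         val   = sort(perm[sizes[1L] + seq_len(sizes[2L])]),
         test  = sort(perm[sizes[1L] + sizes[2L] + seq_len(sizes[3L])]),
         seed  = as.integer(seed)),
    class = "dataset_split")
}
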