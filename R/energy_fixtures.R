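## Synthetic MM/PBSA-style energy component tables: Gaussian per-snapshot
## samples around stated component means, in the TSV schema the energetics
## module consumes.

#' Generate a synthetic energy-component sample table
#'
#' Draws `n_samples` per-snapshot values of the binding enthalpy `dH` and
#' entropy penalty `mTdS` (stored as -T*dS, positive for binding) for each
#' model row, from independent Gaussians with the stated means and standard
#' deviations. Sample statistics converge to the truth as `n_samples` grows.
#'
#' @param seed RNG seed.
#' @param models data.frame with columns `block`, `model`, `replica`,
#'   `dH_mean`, `dH_sd`, `mTdS_mean`, `mTdS_sd` (one row per model row).
#' @param n_samples snapshots per row (>= 2).
#' @param path optional TSV output path.
#' @return data.frame with columns `block`, `model`, `replica`, `snapshot`,
#'   `dH`, `mTdS` (written to `path` as TSV when given).
#' @export
make_energy_table <- function(seed, models, n_samples = 100, path = NULL) {
  stopifnot(n_samples >= 2)
  need <- c("block", "model", "replica", "dH_mean", "dH_sd",
            "mTdS_mean", "mTdS_sd")
  miss <- setdiff(need, names(models))
  if (length(miss) > 0) stop("models lacks columns: ",
                             paste(miss, collapse = ", "))
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    data.frame(block = m$block, model = m$model, replica = m$replica,
               snapshot = seq_len(n_samples),
               dH = rnorm(n_samples, m$dH_mean, m$dH_sd),
               mTdS = rnorm(n_samples, m$mTdS_mean, m$mTdS_sd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
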