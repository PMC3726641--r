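## MM/PBSA-style free-energy bookkeeping. The entropy column is stored as
## the penalty -T*dS (positive for binding), so the combination is a plain
## addition dG = dH + (-T dS); uncertainties combine in quadrature under the
## independence assumption, which reproduces the printed uncertainties of
## the reference tables. Rounding to one decimal happens only at
## presentation, never in arithmetic.

#' Select snapshot index sets for enthalpy and entropy evaluation
#'
#' Enthalpy snapshots are the frames whose time is a multiple of `interval`
#' inside the (half-open) analysis window; entropy snapshots are
#' `entropy_subsample` evenly spaced members of the enthalpy set, first and
#' last included.
#'
#' @param trajectory a `Trajectory` (or a numeric vector of frame times, ps).
#' @param window `c(start, end)` ps; half-open `(start, end]`.
#' @param interval enthalpy snapshot cadence, ps.
#' @param entropy_subsample entropy snapshot count.
#' @return list with `enthalpy` and `entropy` frame-index vectors.
#' @export
select_snapshots <- function(trajectory, window = NULL, interval = 10,
                             entropy_subsample = 20) {
  times <- if (inherits(trajectory, "Trajectory")) frame_times(trajectory)
  else as.numeric(trajectory)
  if (max(times) - min(times) < interval)
    stop("trajectory shorter than the snapshot interval (", interval, " ps)")
  inw <- if (is.null(window)) rep(TRUE, length(times))
  else times > window[1] & times <= window[2]
  on_grid <- abs(times / interval - round(times / interval)) < 1e-9
  enth <- which(inw & on_grid)
  if (length(enth) == 0L) stop("no snapshots at the requested cadence")
  if (length(enth) < entropy_subsample)
    stop("only ", length(enth), " snapshots available; ",
         entropy_subsample, " needed for the entropy subsample")
  ent <- enth[unique(round(seq(1, length(enth),
                               length.out = entropy_subsample)))]
  list(enthalpy = enth, entropy = ent)
}

#' Combine enthalpy and entropy penalty into a binding free energy
#'
#' `dG = dH + (-T dS)`; `sd(dG) = sqrt(sd(dH)^2 + sd(-T dS)^2)` (quadrature,
#' components treated as independent). All arguments are vectorised.
#'
#' @param dH_mean,dH_sd enthalpy mean and sd, kcal/mol.
#' @param mTdS_mean,mTdS_sd entropy penalty (-T dS) mean and sd, kcal/mol.
#' @return data.frame `dG_mean`, `dG_sd` at full precision.
#' @export
combine_free_energy <- function(dH_mean, dH_sd, mTdS_mean, mTdS_sd) {
  if (any(is.na(dH_sd) | is.na(mTdS_sd)))
    warning("single-sample component: sd undefined, propagated as NA")
  data.frame(dG_mean = dH_mean + mTdS_mean,
             dG_sd = sqrt(dH_sd^2 + mTdS_sd^2))
}

#' Per-block relative free energies
#'
#' `ddG = dG - dG_reference` within each block; the reference row is exactly
#' 0. The reference is the block's first row unless a row has
#' `reference == TRUE`.
#'
#' @param table data.frame with columns `block`, `dG_mean` and optionally a
#'   logical `reference`.
#' @return `table` with a `ddG` column appended.
#' @export
relative_free_energy <- function(table) {
  if (!all(c("block", "dG_mean") %in% names(table)))
    stop("table needs columns 'block' and 'dG_mean'")
  table$ddG <- NA_real_
  for (b in unique(table$block)) {
    rows <- which(table$block == b)
    ref <- if ("reference" %in% names(table) && any(table$reference[rows]))
      rows[which(table$reference[rows])[1]] else rows[1]
    table$ddG[rows] <- table$dG_mean[rows] - table$dG_mean[ref]
  }
  table
}

#' Aggregate per-snapshot energy components into a free-energy table
#'
#' Input is the TSV schema of [make_energy_table()]: one row per snapshot
#' with columns `block`, `model`, `replica`, `snapshot`, `dH`, `mTdS`.
#' Replica rows of the same model are kept as separate table rows. The
#' result carries means, sample sds, the combined `dG` with quadrature sd,
#' and per-block `ddG` against each block's first row.
#'
#' @param samples data.frame or TSV path.
#' @return object of class `EnergyTable` (a data.frame).
#' @export
aggregate_components <- function(samples) {
  if (is.character(samples)) {
    if (!file.exists(samples)) stop("no such file: ", samples)
    samples <- utils::read.table(samples, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  }
  need <- c("block", "model", "replica", "snapshot", "dH", "mTdS")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0)
    stop("sample table lacks columns: ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(samples$dH) | !is.finite(samples$mTdS))
  if (length(bad) > 0)
    stop("non-numeric energy component in sample row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  key <- paste(samples$block, samples$model, samples$replica, sep = "\r")
  ukey <- unique(key)
  rows <- lapply(ukey, function(k) {
    sub <- samples[key == k, ]
    if (nrow(sub) < 2L)
      stop("model row '", sub$model[1], "' has fewer than 2 snapshots")
    data.frame(block = sub$block[1], model = sub$model[1],
               replica = sub$replica[1], n_snapshots = nrow(sub),
               dH_mean = mean(sub$dH), dH_sd = stats::sd(sub$dH),
               mTdS_mean = mean(sub$mTdS), mTdS_sd = stats::sd(sub$mTdS),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  energy_table(out)
}

#' Build an EnergyTable from component summaries
#'
#' @param summary data.frame with columns `block`, `model`, `dH_mean`,
#'   `dH_sd`, `mTdS_mean`, `mTdS_sd` (and optionally `replica`,
#'   `reference`).
#' @return object of class `EnergyTable`: the input plus `dG_mean`, `dG_sd`
#'   and per-block `ddG`, all at full precision.
#' @export
energy_table <- function(summary) {
  need <- c("block", "model", "dH_mean", "dH_sd", "mTdS_mean", "mTdS_sd")
  miss <- setdiff(need, names(summary))
  if (length(miss) > 0)
    stop("summary lacks columns: ", paste(miss, collapse = ", "))
  g <- combine_free_energy(summary$dH_mean, summary$dH_sd,
                           summary$mTdS_mean, summary$mTdS_sd)
  summary$dG_mean <- g$dG_mean
  summary$dG_sd <- g$dG_sd
  summary <- relative_free_energy(summary)
  class(summary) <- c("EnergyTable", "data.frame")
  summary
}

#' Presentation layer: round an EnergyTable to one decimal
#'
#' @param x an `EnergyTable`.
#' @param ... unused.
#' @export
format.EnergyTable <- function(x, ...) {
  data.frame(block = x$block, model = x$model,
             dH = sprintf("%.1f +/- %.1f", x$dH_mean, x$dH_sd),
             mTdS = sprintf("%.1f +/- %.1f", x$mTdS_mean, x$mTdS_sd),
             dG = sprintf("%.1f +/- %.1f", x$dG_mean, x$dG_sd),
             ddG = sprintf("%.1f", x$ddG), stringsAsFactors = FALSE)
}

#' @export
print.EnergyTable <- function(x, ...) {
  cat("<EnergyTable> (kcal/mol)\n")
  print(format(x), row.names = FALSE)
  invisible(x)
}

# round-half-away-from-zero to 1 decimal, the convention of printed tables
round1 <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10
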