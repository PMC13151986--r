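#' Substitute below-LOD concentrations with LOD/sqrt(2)
#'
#' Standard single-imputation for analytes reported below the assay's limit
#' of detection.
#'
#' @param values numeric concentrations (ng/g lipid).
#' @param below_lod logical flags, `TRUE` where the value is below the LOD.
#' @param lod numeric LODs (recycled if length 1).
#' @return concentrations with flagged entries replaced by `lod / sqrt(2)`;
#'   unflagged entries are returned unchanged.
#' @export
substitute_lod <- function(values, below_lod, lod) {
  stopifnot(length(values) == length(below_lod))
  lod <- rep_len(lod, length(values))
  if (any(below_lod & (is.na(lod) | lod <= 0), na.rm = TRUE))
    stop("below-LOD entry with missing or non-positive LOD")
  out <- values
  out[which(below_lod)] <- lod[which(below_lod)] / sqrt(2)
  out
}

#' Lipid-normalize serum concentrations
#'
#' Converts wet-weight serum concentrations (ng/mL serum) to lipid-adjusted
#' concentrations (ng/g lipid) by direct division by the serum total lipid
#' concentration, the standard practice for lipophilic analytes.
#'
#' @param serum_conc concentration in ng/mL serum.
#' @param total_lipids serum total lipids in g/L.
#' @return concentration in ng/g lipid
#'   (`serum_conc / total_lipids * 1000`).
#' @export
lipid_normalize <- function(serum_conc, total_lipids) {
  if (any(total_lipids <= 0, na.rm = TRUE))
    stop("total_lipids must be positive")
  serum_conc / total_lipids * 1000
}

#' Serum total lipids from cholesterol and triglycerides
#'
#' Enzymatic summation formula: TL = 2.27 * TC + TG + 0.623 (all in g/L).
#'
#' @param tc total cholesterol, g/L.
#' @param tg triglycerides, g/L.
#' @return total lipids, g/L.
#' @export
total_lipids <- function(tc, tg) 2.27 * tc + tg + 0.623

#' Arithmetic sum of the five PBDE congeners (Sigma5BDE)
#'
#' @param conc matrix or data.frame with the five congener concentrations
#'   (post-substitution), one row per participant.
#' @return numeric vector of row sums; rows with any missing congener are
#'   `NA` (the participant is excluded from Sigma5BDE analyses rather than
#'   imputed).
#' @export
sum_congeners <- function(conc) {
  conc <- as.matrix(conc)
  if (ncol(conc) != 5) stop("expected 5 congener columns")
  out <- rowSums(conc)          # NA propagates: exclusion, not imputation
  if (any(!is.na(out) & out <= 0)) stop("non-positive concentrations")
  out
}

#' Prepare an exposure table
#'
#' Applies LOD/sqrt(2) substitution per congener, computes Sigma5BDE as the
#' arithmetic sum of the five congeners, and adds log2-transformed values so
#' downstream regression coefficients correspond to each doubling of
#' concentration.
#'
#' @param raw data.frame with columns `bde28 ... bde153` (ng/g lipid,
#'   censored at the LOD where flagged), `<congener>_below_lod` flags and
#'   `<congener>_lod` values, plus `participant_id`.
#' @return data.frame with substituted concentrations, below-LOD flags,
#'   `sum5`, `excluded_sum5`, and `log2_<analyte>` columns.
#' @export
prepare_exposures <- function(raw) {
  cg <- names_congeners()
  stopifnot(all(cg %in% names(raw)))
  out <- data.frame(participant_id = raw$participant_id)
  for (j in cg) {
    flag_col <- paste0(j, "_below_lod")
    lod_col <- paste0(j, "_lod")
    flags <- if (flag_col %in% names(raw)) raw[[flag_col]] else
      rep(FALSE, nrow(raw))
    lods <- if (lod_col %in% names(raw)) raw[[lod_col]] else NA_real_
    out[[j]] <- substitute_lod(raw[[j]], flags, lods)
    out[[flag_col]] <- flags
  }
  out$sum5 <- sum_congeners(out[cg])
  out$excluded_sum5 <- is.na(out$sum5)
  for (j in c(cg, "sum5")) out[[paste0("log2_", j)]] <- log2(out[[j]])
  out
}

#' Descriptive statistics for exposure analytes
#'
#' Mirrors the usual exposure summary table: n, min, max, arithmetic mean,
#' SD, quartiles, geometric mean with a 95 percent confidence interval
#' (t-interval on the natural-log scale, back-transformed), and percent of
#' samples above the LOD.
#'
#' @param prepared output of [prepare_exposures()].
#' @param conf_level confidence level for the geometric-mean interval.
#' @return data.frame, one row per analyte (five congeners plus Sigma5BDE).
#' @export
describe_exposures <- function(prepared, conf_level = 0.95) {
  cg <- names_congeners()
  rows <- lapply(c(cg, "sum5"), function(j) {
    v <- prepared[[j]]
    v <- v[!is.na(v)]
    if (length(v) < 2) stop("need at least 2 observations per analyte")
    if (any(v <= 0)) stop("non-positive concentration in analyte ", j)
    lg <- log(v)
    n <- length(v)
    half <- stats::qt(1 - (1 - conf_level) / 2, n - 1) * stats::sd(lg) / sqrt(n)
    pct_lod <- if (j == "sum5") NA_real_ else {
      flags <- prepared[[paste0(j, "_below_lod")]][!is.na(prepared[[j]])]
      100 * (1 - mean(flags))
    }
    data.frame(analyte = j, n = n, min = min(v), max = max(v),
               mean = mean(v), sd = stats::sd(v),
               p25 = as.numeric(stats::quantile(v, 0.25)),
               median = stats::median(v),
               p75 = as.numeric(stats::quantile(v, 0.75)),
               geomean = exp(mean(lg)),
               geomean_lo = exp(mean(lg) - half),
               geomean_hi = exp(mean(lg) + half),
               pct_above_lod = pct_lod)
  })
  do.call(rbind, rows)
}

#' Exposure-outcome Pearson correlation table
#'
#' Bivariate Pearson correlations between each log2 exposure and each
#' outcome T-score, with two-sided p-values from the t transform of r on
#' n - 2 degrees of freedom, computed on pairwise-complete observations.
#'
#' @param log2_exposures data.frame of log2 exposure columns.
#' @param outcomes data.frame of outcome T-score columns.
#' @return data.frame with columns `exposure`, `outcome`, `n`, `r`, `p`,
#'   `undefined` (`TRUE` when either variable has zero variance, in which
#'   case `r` and `p` are `NA`).
#' @export
correlate_exposure_outcomes <- function(log2_exposures, outcomes) {
  grid <- expand.grid(exposure = names(log2_exposures),
                      outcome = names(outcomes),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- log2_exposures[[grid$exposure[i]]]
    y <- outcomes[[grid$outcome[i]]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3) stop("need at least 3 pairwise-complete observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(grid[i, ], n = n, r = NA_real_, p = NA_real_,
                        undefined = TRUE))
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(grid[i, ], n = n, r = unname(ct$estimate), p = ct$p.value,
               undefined = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
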