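#' Maximum metabolic rate from QC-passed MO2 values
#'
#' MMR is defined operationally as the single highest MO2 value recorded at a
#' temperature (typically the acclimation temperature, where handling stress
#' and spontaneous activity drive the fish toward its ceiling). Input should
#' be mass-standardized with the MMR exponent (b = 0.937).
#'
#' @param x QC-passed MO2 values, mg O2 kg^-1 h^-1.
#' @return The maximum, mg O2 kg^-1 h^-1.
#' @export
estimate_mmr <- function(x) {
  x <- as.numeric(x[is.finite(x)])
  if (length(x) == 0) stop("no observations to take MMR from")
  max(x)
}

#' Absolute and factorial aerobic scope
#'
#' AAS = MMR - SMR (capacity above maintenance, mg O2 kg^-1 h^-1);
#' FAS = MMR / SMR (dimensionless). An MMR below SMR is physiologically
#' impossible and is returned flagged rather than silently.
#'
#' @param smr,mmr Standard and maximum metabolic rate, mg O2 kg^-1 h^-1.
#' @return List with `aas`, `fas` and logical `flagged` (TRUE when mmr < smr).
#' @examples
#' aerobic_scope(50, 150)  # AAS 100, FAS 3
#' @export
aerobic_scope <- function(smr, mmr) {
  if (smr <= 0) stop("smr must be positive")
  flagged <- mmr < smr
  if (flagged)
    warning("MMR below SMR: aerobic scope flagged as invalid")
  list(aas = mmr - smr, fas = mmr / smr, flagged = flagged)
}

#' Q10 temperature coefficient
#'
#' The factor by which a rate changes over a 10 degree C increase:
#' \deqn{Q_{10} = (R_2 / R_1)^{10 / (t_2 - t_1)}}
#'
#' @param r1,r2 Rates at temperatures `t1` and `t2` (positive).
#' @param t1,t2 Temperatures, degrees C (`t1 != t2`).
#' @return Dimensionless Q10.
#' @examples
#' q10(50, 100, 15, 25)       # 2: doubling per decade
#' q10(28.6, 53.8, 5, 15)     # ~1.88
#' @export
q10 <- function(r1, r2, t1, t2) {
  if (any(r1 <= 0) || any(r2 <= 0)) stop("rates must be positive")
  if (any(t1 == t2)) stop("t1 and t2 must differ")
  (r2 / r1)^(10 / (t2 - t1))
}

#' Per-fish metabolic phenotypes from MO2 records
#'
#' Derives the full phenotype set of one fish from its quality-filtered MO2
#' records: SMR per hold temperature (normal-mixture lowest component on
#' b = 0.948 standardized values), MMR at the starting temperature (highest
#' b = 0.937 standardized value), absolute and factorial aerobic scope at the
#' starting temperature, and Q10 of SMR between the extreme hold temperatures
#' of the arm.
#'
#' Temperature bins with fewer than `min_obs` QC-passed cycles get no SMR
#' estimate (recorded as NA and listed in `$skipped`), rather than an
#' unreliable mixture fit.
#'
#' @param records MO2 record data frame from [process_trace()].
#' @param fish_id,origin Identifiers attached to the output; default to the
#'   trial metadata in `records`.
#' @param mmr_temp Temperature at which MMR is taken; defaults to the first
#'   (highest-coverage) hold, i.e. the acclimation temperature.
#' @param q10_pair Temperatures `c(t1, t2)` for Q10; defaults to the extreme
#'   holds of the arm (5/15 for a cold challenge, 20/30 for a heat challenge).
#' @param min_obs Minimum QC-passed cycles per temperature for an SMR fit.
#' @param ... Passed to [estimate_smr()].
#' @return An object of class `phenotype_set`: list with `fish_id`, `origin`,
#'   `smr` (named by temperature), `smr_fits`, `mmr`, `mmr_temp`, `aas`,
#'   `fas`, `q10`, `q10_pair`, `skipped`.
#' @export
estimate_phenotypes <- function(records, fish_id = records$trial_id[1],
                                origin = NA_character_, mmr_temp = NULL,
                                q10_pair = NULL, min_obs = 10, ...) {
  ok <- records[records$passed_qc & !is.na(records$temperature_bin), ,
                drop = FALSE]
  if (nrow(ok) == 0) stop("no QC-passed on-hold records for fish ", fish_id)
  temps <- sort(unique(ok$temperature_bin))

  smr_fits <- list(); smr <- stats::setNames(rep(NA_real_, length(temps)),
                                             temps)
  skipped <- numeric(0)
  for (tp in temps) {
    v <- ok$mo2_std_smr[ok$temperature_bin == tp]
    if (length(v) < min_obs) { skipped <- c(skipped, tp); next }
    f <- estimate_smr(v, min_obs = min_obs, temperature = tp, ...)
    smr_fits[[as.character(tp)]] <- f
    smr[as.character(tp)] <- f$smr
  }

  if (is.null(mmr_temp)) {
    cover <- table(ok$temperature_bin)
    mmr_temp <- as.numeric(names(cover)[which.max(cover)])
  }
  mmr <- estimate_mmr(ok$mo2_std_mmr[ok$temperature_bin == mmr_temp])

  aas <- fas <- NA_real_
  if (!is.na(smr[as.character(mmr_temp)])) {
    sc <- aerobic_scope(smr[[as.character(mmr_temp)]], mmr)
    aas <- sc$aas; fas <- sc$fas
  }

  if (is.null(q10_pair)) q10_pair <- range(temps)
  q10_val <- NA_real_
  r1 <- smr[as.character(q10_pair[1])]; r2 <- smr[as.character(q10_pair[2])]
  if (length(r1) && length(r2) && !is.na(r1) && !is.na(r2))
    q10_val <- q10(r1[[1]], r2[[1]], q10_pair[1], q10_pair[2])

  structure(list(fish_id = fish_id, origin = origin, smr = smr,
                 smr_fits = smr_fits, mmr = mmr, mmr_temp = mmr_temp,
                 aas = aas, fas = fas, q10 = q10_val, q10_pair = q10_pair,
                 skipped = skipped), class = "phenotype_set")
}

#' @export
print.phenotype_set <- function(x, ...) {
  cat(sprintf("<phenotype_set> %s (%s)\n", x$fish_id, x$origin))
  cat("  SMR:", paste(sprintf("%s C: %.1f", names(x$smr), x$smr),
                      collapse = ", "), "\n")
  cat(sprintf("  MMR @ %g C: %.1f | AAS %.1f | FAS %.2f | Q10(%g-%g C) %.2f\n",
              x$mmr_temp, x$mmr, x$aas, x$fas, x$q10_pair[1], x$q10_pair[2],
              x$q10))
  if (length(x$skipped))
    cat("  no SMR estimate (too few cycles) at:",
        paste(x$skipped, collapse = ", "), "C\n")
  invisible(x)
}

#' Flatten phenotype sets into a tidy table
#'
#' @param phenotypes List of `phenotype_set` objects.
#' @return Data frame with columns `fish_id`, `origin`, `metric`
#'   (`SMR`/`MMR`/`AAS`/`FAS`/`Q10`), `temperature` (a single hold for SMR and
#'   MMR, `"t1-t2"` for Q10) and `value`.
#' @export
phenotype_table <- function(phenotypes) {
  rows <- lapply(phenotypes, function(p) {
    stopifnot(inherits(p, "phenotype_set"))
    rbind(
      data.frame(fish_id = p$fish_id, origin = p$origin, metric = "SMR",
                 temperature = names(p$smr), value = unname(p$smr)),
      data.frame(fish_id = p$fish_id, origin = p$origin,
                 metric = c("MMR", "AAS", "FAS"),
                 temperature = as.character(p$mmr_temp),
                 value = c(p$mmr, p$aas, p$fas)),
      data.frame(fish_id = p$fish_id, origin = p$origin, metric = "Q10",
                 temperature = paste(p$q10_pair, collapse = "-"),
                 value = p$q10))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
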