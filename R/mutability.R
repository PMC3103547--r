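# mutability: Z-score standardization of the 19-substitution effect
# distribution at a site, the half-standard-deviation (HSTD) threshold, and
# the tolerance / specificity / pKa-sensitivity classification rules.

#' Site profile: distribution statistics of the 19 substitution effects
#'
#' Population statistics (divide-by-n; \code{std_mode = "sample"} switches to
#' divide-by-(n-1)). HSTD is half the standard deviation. Z-scores are
#' (x - mean) / sd.
#'
#' @param effects exactly 19 finite values (kcal/mol for energy metrics, pK
#'   units for pka).
#' @param metric one of "folding", "binding", "pka".
#' @param site_id optional site label.
#' @param substitutions optional names for the 19 effects (one-letter codes).
#' @param std_mode "population" (default) or "sample".
#' @return a \code{SiteProfile} with effects, mean, std, hstd and zscores.
#' @export
site_profile <- function(effects, metric = c("folding", "binding", "pka"),
                         site_id = NULL, substitutions = NULL,
                         std_mode = c("population", "sample")) {
  metric <- match.arg(metric)
  std_mode <- match.arg(std_mode)
  effects <- as.numeric(effects)
  if (length(effects) != 19) {
    stop("a site profile needs exactly 19 substitution effects, got ",
         length(effects))
  }
  if (!all(is.finite(effects))) stop("non-finite effect values")
  mu <- mean(effects)
  n <- length(effects)
  sdev <- if (std_mode == "population") {
    sqrt(sum((effects - mu)^2) / n)
  } else {
    stats::sd(effects)
  }
  if (sdev == 0) stop("degenerate distribution: zero standard deviation")
  if (!is.null(substitutions)) names(effects) <- substitutions
  out <- list(site_id = site_id, metric = metric, effects = effects,
              mean = mu, std = sdev, hstd = sdev / 2,
              zscores = (effects - mu) / sdev, std_mode = std_mode)
  class(out) <- "SiteProfile"
  out
}

#' @export
print.SiteProfile <- function(x, ...) {
  cat(sprintf("SiteProfile %s [%s]: mean %.3f, std %.3f, HSTD %.3f\n",
              if (is.null(x$site_id)) "" else x$site_id, x$metric,
              x$mean, x$std, x$hstd))
  invisible(x)
}

#' Tolerance classification of a site
#'
#' Non-tolerable when the magnitude of the mean substitution effect exceeds
#' the HSTD threshold (strict inequality); tolerable otherwise. Energy
#' metrics only.
#'
#' @param p a \code{SiteProfile} with metric "folding" or "binding".
#' @return "tolerable" or "non-tolerable".
#' @export
classify_tolerance <- function(p) {
  stopifnot(inherits(p, "SiteProfile"))
  if (p$metric == "pka") stop("use classify_pka for the pka metric")
  if (abs(p$mean) > p$hstd) "non-tolerable" else "tolerable"
}

#' Specificity classification of a site
#'
#' Specific when more than 20\% of the 19 substitutions have effects whose
#' magnitude exceeds the HSTD and those exceeding effects include both
#' favourable and unfavourable (positive and negative) directions; otherwise
#' non-specific.
#'
#' @param p a \code{SiteProfile} with an energy metric.
#' @return "specific" or "non-specific".
#' @export
classify_specificity <- function(p) {
  stopifnot(inherits(p, "SiteProfile"))
  if (p$metric == "pka") stop("use classify_pka for the pka metric")
  exceed <- p$effects[abs(p$effects) > p$hstd]
  if (length(exceed) / length(p$effects) > 0.20 &&
      any(exceed > 0) && any(exceed < 0)) "specific" else "non-specific"
}

#' pKa sensitivity and specificity of a site
#'
#' Operates on the 19 cumulative absolute pKa shifts (one per substitution).
#' Sensitive when their mean exceeds 2 pK units; specific when the spread
#' (max - min) between substitution types exceeds 2 pK units.
#'
#' @param sum_shifts 19 non-negative cumulative shifts (pK units).
#' @return named character vector with sensitivity and specificity labels.
#' @export
classify_pka <- function(sum_shifts) {
  sum_shifts <- as.numeric(sum_shifts)
  if (length(sum_shifts) != 19) stop("expected 19 cumulative shifts")
  if (any(!is.finite(sum_shifts)) || any(sum_shifts < 0)) {
    stop("cumulative pKa shifts must be finite and non-negative")
  }
  c(sensitivity = if (mean(sum_shifts) > 2.0) "sensitive" else "non-sensitive",
    specificity = if (max(sum_shifts) - min(sum_shifts) > 2.0) "specific"
                  else "non-specific")
}

#' Classify a site profile (both rules at once)
#'
#' @param p a \code{SiteProfile} (energy metric).
#' @param prose_override optional user-supplied label overriding the formal
#'   tolerance rule; recorded alongside, never replacing, the formal label.
#' @return a \code{SiteClassification}.
#' @export
classify_site <- function(p, prose_override = NULL) {
  out <- list(site_id = p$site_id, metric = p$metric,
              tolerance = classify_tolerance(p),
              specificity = classify_specificity(p),
              mean = p$mean, hstd = p$hstd,
              prose_override = prose_override,
              rationale = sprintf(
                "|mean| %.3f %s HSTD %.3f; %d/19 beyond HSTD (%s signs)",
                abs(p$mean),
                if (abs(p$mean) > p$hstd) ">" else "<=", p$hstd,
                sum(abs(p$effects) > p$hstd),
                if (any(p$effects[abs(p$effects) > p$hstd] > 0) &&
                    any(p$effects[abs(p$effects) > p$hstd] < 0)) "both"
                else "one"))
  class(out) <- "SiteClassification"
  out
}

#' @export
print.SiteClassification <- function(x, ...) {
  cat(sprintf("SiteClassification %s [%s]: %s %s%s\n",
              if (is.null(x$site_id)) "" else x$site_id, x$metric,
              x$tolerance, x$specificity,
              if (!is.null(x$prose_override))
                paste0(" (prose override: ", x$prose_override, ")") else ""))
  invisible(x)
}

#' Write a site report (JSON + TSV)
#'
#' Per-substitution effects and Z-scores (ascending), the formal labels, and
#' any prose-override annotation. The specificity rule reading (">20% of
#' substitutions beyond HSTD in both directions") is logged in every report.
#'
#' @param profiles list of \code{SiteProfile}s.
#' @param classifications list of \code{SiteClassification}s (parallel).
#' @param path output path without extension; \code{<path>.json} and
#'   \code{<path>.tsv} are written.
#' @return the report list, invisibly.
#' @export
site_report <- function(profiles, classifications, path) {
  stopifnot(length(profiles) == length(classifications), length(profiles) >= 1)
  sections <- lapply(seq_along(profiles), function(k) {
    p <- profiles[[k]]; cl <- classifications[[k]]
    ord <- order(p$zscores)
    list(site_id = p$site_id, metric = p$metric,
         mean = p$mean, std = p$std, hstd = p$hstd, std_mode = p$std_mode,
         substitutions = names(p$effects)[ord],
         effects = unname(p$effects[ord]),
         zscores = unname(p$zscores[ord]),
         tolerance = cl$tolerance, specificity = cl$specificity,
         prose_override = cl$prose_override, rationale = cl$rationale)
  })
  report <- list(
    specificity_rule = paste("specific iff >20% of the 19 substitutions have",
                             "|effect| > HSTD and the exceeding effects",
                             "include both signs"),
    std_mode = profiles[[1]]$std_mode,
    sections = sections)
  jsonlite::write_json(report, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  tsv <- do.call(rbind, lapply(sections, function(sec) {
    data.frame(site = sec$site_id, metric = sec$metric,
               aa = if (is.null(sec$substitutions)) NA else sec$substitutions,
               effect = sec$effects, zscore = sec$zscores,
               mean = sec$mean, hstd = sec$hstd,
               tolerance = sec$tolerance, specificity = sec$specificity,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tsv, paste0(path, ".tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(report)
}

#' Read a site report back
#'
#' @param path path used in \code{site_report} (without extension).
#' @return list with profiles and classifications reconstructed from the
#'   JSON report.
#' @export
read_site_report <- function(path) {
  rep <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sections <- rep$sections
  if (is.data.frame(sections)) {
    sections <- lapply(seq_len(nrow(sections)), function(k) as.list(sections[k, ]))
  }
  profiles <- lapply(sections, function(sec) {
    site_profile(unlist(sec$effects), sec$metric, site_id = sec$site_id,
                 substitutions = unlist(sec$substitutions),
                 std_mode = sec$std_mode)
  })
  classifications <- lapply(profiles, classify_site)
  list(profiles = profiles, classifications = classifications)
}
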