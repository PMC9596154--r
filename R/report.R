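#' Render a human-readable analysis report
#'
#' Summarizes the RSA results: per-ROI coefficient tables, the list of
#' coefficients surviving FDR correction, the imminence-preference
#' classification of the cohort, the predominance comparison, and an echo
#' of the configuration used. Regenerating the report from the same saved
#' tables is idempotent.
#'
#' @param rsa Result list from [run_rsa()].
#' @param classification Data frame from [classify_imminence_preference()].
#' @param predominance Optional data frame from [predominance_test()].
#' @param config Optional `pipeline_config` to echo.
#' @return Character vector of report lines, invisibly printable with
#'   `writeLines()`.
#' @export
render_report <- function(rsa, classification = NULL, predominance = NULL,
                          config = NULL) {
  fmt <- function(x) formatC(x, digits = 3, format = "g")
  lines <- c("RSA of helping under threat - analysis report",
             strrep("=", 46), "")
  lines <- c(lines, sprintf("Kendall variant: %s; FDR level alpha = %s; %d p-values in FDR pool",
                            rsa$variant, fmt(rsa$alpha), rsa$fdr_pool_size), "")
  for (roi in unique(rsa$models$roi)) {
    sub <- rsa$models[rsa$models$roi == roi, ]
    lines <- c(lines, sprintf("ROI: %s (n = %d rows)", roi, sub$n_rows[1]))
    lines <- c(lines, sprintf("  %-20s beta=%8s se=%8s t=%7s p=%8s p_fdr=%8s",
                              sub$term, fmt(sub$beta), fmt(sub$se),
                              fmt(sub$t), fmt(sub$p),
                              ifelse(is.na(sub$p_fdr), "-", fmt(sub$p_fdr))))
  }
  sig <- rsa$models[!is.na(rsa$models$significant) & rsa$models$significant, ]
  lines <- c(lines, "", "Significant after FDR:")
  if (!nrow(sig)) {
    lines <- c(lines, "  no ROI passed FDR")
  } else {
    lines <- c(lines, sprintf("  %s: %s (beta=%s, p_fdr=%s)", sig$roi,
                              sig$term, fmt(sig$beta), fmt(sig$p_fdr)))
  }
  if (!is.null(classification)) {
    lines <- c(lines, "", "Imminence preference (subjects helping more under each condition):",
               sprintf("  %-14s n=%d", classification$imminence_class,
                       classification$n))
  }
  if (!is.null(predominance)) {
    lines <- c(lines, "", "Predominance (threat vs distress coding, paired Wilcoxon):")
    lines <- c(lines, sprintf("  %-14s %-9s direction=%-9s p=%8s p_fdr=%8s%s",
                              predominance$roi, predominance$condition,
                              predominance$direction, fmt(predominance$p),
                              fmt(predominance$p_fdr),
                              ifelse(predominance$significant, " *", "")))
  }
  if (!is.null(config)) {
    lines <- c(lines, "", "Configuration:",
               paste0("  ", utils::capture.output(utils::str(
                 lapply(unclass(config), function(x)
                   if (is.object(x)) unclass(x) else x), give.attr = FALSE))))
  }
  lines
}
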