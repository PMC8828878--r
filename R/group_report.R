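#' Pointwise average of sampled series
#'
#' Averages region- or subject-level sampled BOLD series on identical
#' grids, the "overall brain performance" aggregate: averaging is done on
#' the data before fitting, not on fitted parameters.
#'
#' @param members list of [time_series()] on identical grids.
#' @return A [time_series()], the pointwise mean.
#' @export
average_series <- function(members) {
  stopifnot(is.list(members), length(members) >= 1L)
  ref <- members[[1L]]
  for (m in members)
    if (!same_grid(ref, m))
      stop("all members must share the sampling grid", call. = FALSE)
  v <- rowMeans(vapply(members, function(m) m$values,
                       numeric(length(ref$values))))
  time_series(v, dt = ref$dt, t0 = ref$t0)
}

#' Group-by-condition capacity report
#'
#' Tabulates the derived capacity parameters for a set of fitted cells
#' (e.g. group x condition), always stating which cell's fitted amplitude
#' is the normalization reference. When behavioural response times are
#' supplied, the ratio `T_r / T_c` is reported per cell together with the
#' descending ordering of time constants, optionally checked against an
#' expected ordering. Cells whose fitted activity amplitude is anomalously
#' low relative to the most active cell are annotated — low activity does
#' not by itself imply high processing capacity and may instead reflect an
#' activation deficit.
#'
#' @param fits named list of [two_state_params()] fits, one per cell.
#' @param rts optional named numeric vector of mean behavioural response
#'   times `T_r` (s), names matching `fits`.
#' @param reference name (or index) of the cell whose amplitude normalizes
#'   the relative capacities; default the first cell.
#' @param expected_order optional character vector of cell names in the
#'   expected descending-`T_c` order.
#' @param hrf optional [hrf_params()] (or named list of them) used to
#'   compute time-to-peak of the predicted BOLD per cell.
#' @param amp_ratio_pairs optional list of 2-vectors of cell names
#'   (numerator, denominator); fitted amplitude ratios, e.g. the
#'   Incongruent-to-Congruent input ratio `alpha_IC / alpha_C` under the
#'   shared-storage assumption.
#' @param low_activity_frac amplitude fraction of the maximum below which a
#'   cell is annotated (default 0.5).
#' @return list of class `capacity_report`: `table` (data.frame),
#'   `reference`, `ordering`, `ordering_matches`, `amp_ratios`,
#'   `annotations`.
#' @export
capacity_table <- function(fits, rts = NULL, reference = 1L,
                           expected_order = NULL, hrf = NULL,
                           amp_ratio_pairs = NULL,
                           low_activity_frac = 0.5) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  if (is.null(names(fits)) || any(names(fits) == ""))
    stop("'fits' must be a fully named list of cells", call. = FALSE)
  ref_name <- if (is.numeric(reference)) names(fits)[reference] else reference
  if (!ref_name %in% names(fits))
    stop(sprintf("reference cell '%s' not among the fits", ref_name),
         call. = FALSE)
  a_ref <- fits[[ref_name]]$a
  hrf_for <- function(nm) {
    if (is.null(hrf)) return(NULL)
    if (inherits(hrf, "hrf_params")) return(hrf)
    hrf[[nm]]
  }
  rows <- lapply(names(fits), function(nm) {
    p <- fits[[nm]]
    d <- derive_capacities(p, reference_amp = a_ref, hrf = hrf_for(nm))
    data.frame(cell = nm, a = p$a, k_per_s = p$k,
               t_const_s = d$t_const,
               rel_processing = d$rel_processing,
               rel_storage = d$rel_storage,
               t_peak_s = d$t_peak,
               T_r_s = if (!is.null(rts) && nm %in% names(rts))
                 rts[[nm]] else NA_real_)
  })
  tab <- do.call(rbind, rows)
  tab$rt_over_tc <- tab$T_r_s / tab$t_const_s

  ordering <- tab$cell[order(-tab$t_const_s)]
  ordering_matches <- if (!is.null(expected_order))
    identical(as.character(ordering), as.character(expected_order)) else NA

  amp_ratios <- NULL
  if (!is.null(amp_ratio_pairs)) {
    amp_ratios <- vapply(amp_ratio_pairs, function(pr)
      fits[[pr[1]]]$a / fits[[pr[2]]]$a, 0)
    names(amp_ratios) <- vapply(amp_ratio_pairs,
                                function(pr) paste(pr, collapse = "/"), "")
  }
  a_max <- max(tab$a)
  low <- tab$cell[tab$a < low_activity_frac * a_max]
  annotations <- if (length(low))
    sprintf(paste("cells %s show anomalously low fitted activity relative",
                  "to the most active cell; low activity may reflect an",
                  "activation deficit rather than high processing capacity"),
            paste(low, collapse = ", "))
  else character(0)

  structure(list(table = tab, reference = ref_name,
                 ordering = if (length(fits) > 1L) ordering else NULL,
                 ordering_matches = ordering_matches,
                 amp_ratios = amp_ratios, annotations = annotations),
            class = "capacity_report")
}

#' @export
print.capacity_report <- function(x, ...) {
  cat(sprintf("Capacity report (reference amplitude: cell '%s')\n",
              x$reference))
  print(x$table, row.names = FALSE, digits = 4)
  if (!is.null(x$ordering))
    cat("Descending T_c ordering:", paste(x$ordering, collapse = " > "),
        "\n")
  if (!is.na(x$ordering_matches) && length(x$ordering_matches))
    cat("Matches expected ordering:", x$ordering_matches, "\n")
  if (!is.null(x$amp_ratios)) {
    cat("Amplitude ratios:\n")
    for (nm in names(x$amp_ratios))
      cat(sprintf("  %s = %.4g\n", nm, x$amp_ratios[[nm]]))
  }
  for (a in x$annotations) cat("Note:", a, "\n")
  invisible(x)
}

#' Render a capacity report as markdown
#'
#' @param report a [capacity_table()] result.
#' @return character vector of markdown lines.
#' @export
report_markdown <- function(report) {
  stopifnot(inherits(report, "capacity_report"))
  tab <- report$table
  num <- function(v) ifelse(is.na(v), "--", sprintf("%.4g", v))
  lines <- c("# Capacity report",
             "",
             sprintf("Normalization reference: `%s` (its fitted amplitude is alpha/m of the reference condition).",
                     report$reference),
             "",
             paste("| cell | a | k (1/s) | T_c (s) | p/alpha | m/alpha |",
                   "T_y (s) | T_r (s) | T_r/T_c |"),
             "|---|---|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(tab)))
    lines <- c(lines, sprintf("| %s | %s | %s | %s | %s | %s | %s | %s | %s |",
                              tab$cell[i], num(tab$a[i]), num(tab$k_per_s[i]),
                              num(tab$t_const_s[i]),
                              num(tab$rel_processing[i]),
                              num(tab$rel_storage[i]), num(tab$t_peak_s[i]),
                              num(tab$T_r_s[i]), num(tab$rt_over_tc[i])))
  if (!is.null(report$ordering))
    lines <- c(lines, "",
               paste("Descending T_c ordering:",
                     paste(report$ordering, collapse = " > ")))
  if (!is.null(report$amp_ratios))
    lines <- c(lines, "",
               paste0("Amplitude ratios: ",
                      paste(sprintf("%s = %.4g", names(report$amp_ratios),
                                    report$amp_ratios), collapse = ", ")))
  for (a in report$annotations) lines <- c(lines, "", paste("Note:", a))
  lines
}
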