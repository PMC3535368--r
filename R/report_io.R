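#' Write peak-intensity time courses as a long-format CSV
#'
#' Columns: `time_min,intensity,label,state,isomer,direction`.
#'
#' @param tcs A [time_course()] or list thereof.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(tcs, path) {
  if (inherits(tcs, "time_course")) tcs <- list(tcs)
  stopifnot(all(vapply(tcs, inherits, logical(1), "time_course")))
  long <- do.call(rbind, lapply(tcs, function(tc) {
    data.frame(time_min = tc$times, intensity = tc$intensities,
               label = tc$label, state = tc$state, isomer = tc$isomer,
               direction = tc$direction, stringsAsFactors = FALSE)
  }))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read time courses from a long-format CSV
#'
#' Expects the columns written by [write_timecourses()]:
#' `time_min,intensity,label,state,isomer,direction`.
#'
#' @param path File path.
#' @return List of [time_course()] objects, one per
#'   (label, state, isomer) combination.
#' @export
read_timecourses <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(isomer = "character"))
  need <- c("time_min", "intensity", "label", "state", "isomer",
            "direction")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("time-course file misses column(s): ", paste(miss, collapse = ", "))
  }
  key <- paste(df$label, df$state, df$isomer, sep = "\r")
  lapply(split(df, key), function(g) {
    g <- g[order(g$time_min), ]
    time_course(g$time_min, g$intensity, direction = g$direction[1],
                label = g$label[1], state = g$state[1],
                isomer = g$isomer[1])
  })
}

#' Write a binding report as CSV and JSON
#'
#' The CSV holds the per-row report; the JSON additionally carries the
#' A/B ratio table.  Units are embedded in column names (`T_min`,
#' `K_d_M`; `k_obs` in per molar per second, `k_off` in per second).
#'
#' @param report A `"binding_report"` from [build_table()].
#' @param csv_path,json_path Output file paths (`NULL` to skip one).
#' @return Invisibly, a list of the written paths.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "binding_report"))
  if (!is.null(csv_path)) {
    write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    payload <- list(report = as.data.frame(report),
                    ratios = attr(report, "ratios"))
    jsonlite::write_json(payload, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  invisible(list(csv = csv_path, json = json_path))
}

#' Round-style display formatting of a binding report
#'
#' Applies the publication rounding conventions: `k_obs` to 2 decimals,
#' `K_d` to 3 significant figures, `k_off` to 2 significant figures,
#' `T` to the nearest minute.  The underlying report keeps full
#' precision.
#'
#' @param report A `"binding_report"`.
#' @return A data frame of formatted character columns.
#' @export
format_report <- function(report) {
  stopifnot(inherits(report, "binding_report"))
  data.frame(
    state = report$state, isomer = report$isomer,
    T_min = sprintf("%.0f", report$T_min),
    k_obs = sprintf("%.2f", report$k_obs),
    K_d = ifelse(is.na(report$K_d_M), "",
                 formatC(signif(report$K_d_M, 3), format = "g")),
    k_off = ifelse(is.na(report$k_off), "",
                   formatC(signif(report$k_off, 2), format = "g")),
    mode = report$mode, stringsAsFactors = FALSE)
}

#' @export
print.binding_report <- function(x, ...) {
  cat("binding report (", nrow(x), " state/orientation rows)\n", sep = "")
  print(format_report(x))
  r <- attr(x, "ratios")
  if (!is.null(r)) {
    cat("A/B ratios per state:\n")
    print(r)
  }
  invisible(x)
}
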