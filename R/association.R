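# Regression of log-transformed geographic range size on the maximum
# thermal tolerance range.

#' Regress log range size on maximum thermal tolerance range
#'
#' Ordinary least squares of `y = log(range, base)` on
#' `x = max_range_C` across species, for the latitudinal or longitudinal
#' range. Species with non-positive range on the chosen axis are excluded
#' with a warning (the log is undefined there). The coefficient of
#' determination is invariant to the log base; significance is the
#' two-sided t test of the correlation with n - 2 degrees of freedom.
#'
#' @param summaries a `species_thermal_summary` (see [summarize_species()])
#'   or any data.frame with `species`, `max_range_C` and
#'   `lat_range`/`lon_range` columns.
#' @param axis `"lat"` or `"lon"`.
#' @param log_base base of the logarithm applied to the range (default 10).
#' @return list of class `range_regression`: `axis`, `n`, `slope`,
#'   `intercept`, `r`, `r_squared`, `p_value`, `excluded` (species ids),
#'   `log_base`, and `data` (the x/y pairs used).
#' @export
tolerance_range_regression <- function(summaries, axis = c("lat", "lon"),
                                       log_base = 10) {
  axis <- match.arg(axis)
  col <- paste0(axis, "_range")
  stopifnot(all(c("species", col, "max_range_C") %in% names(summaries)))
  rng <- summaries[[col]]
  usable <- is.finite(rng) & rng > 0 & is.finite(summaries$max_range_C)
  excluded <- summaries$species[!usable]
  if (length(excluded)) {
    warning("excluded species with non-positive or missing ", axis,
            " range: ", paste(excluded, collapse = ", "))
  }
  if (sum(usable) < 3L) {
    stop("fewer than 3 usable species for the ", axis, " regression",
         call. = FALSE)
  }
  x <- summaries$max_range_C[usable]
  y <- log(rng[usable], base = log_base)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in ", if (stats::sd(x) == 0) "x" else "y",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  n <- length(x)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  structure(list(
    axis = axis, n = n,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r = r, r_squared = r^2,
    p_value = 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE),
    excluded = excluded, log_base = log_base,
    data = data.frame(species = summaries$species[usable], x = x, y = y)
  ), class = "range_regression")
}

#' @export
print.range_regression <- function(x, ...) {
  cat(sprintf(
    "%s range vs max thermal tolerance range: n = %d, R^2 = %.3f, p = %.3g\n",
    x$axis, x$n, x$r_squared, x$p_value))
  cat(sprintf("  log%g(range) = %.4f + %.4f * max_range_C\n",
              x$log_base, x$intercept, x$slope))
  invisible(x)
}

#' Write regression coefficients (and an optional labelled scatter plot)
#'
#' @param results a list of `range_regression` objects (one or more axes).
#' @param dir output directory (created if needed).
#' @param plot if `TRUE` and ggplot2 is available, writes a per-species
#'   labelled scatter plot `association_plot.png`.
#' @return invisible character vector of written file paths.
#' @export
association_report <- function(results, dir, plot = FALSE) {
  if (inherits(results, "range_regression")) results <- list(results)
  if (!length(results)) stop("no regression results", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- do.call(rbind, lapply(results, function(r) data.frame(
    axis = r$axis, n = r$n, slope = r$slope, intercept = r$intercept,
    r = r$r, r_squared = r$r_squared, p_value = r$p_value,
    log_base = r$log_base,
    excluded = paste(r$excluded, collapse = ";")
  )))
  csv <- file.path(dir, "association.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  js <- file.path(dir, "association.json")
  jsonlite::write_json(tab, js, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  paths <- c(csv, js)
  if (plot && requireNamespace("ggplot2", quietly = TRUE)) {
    pd <- do.call(rbind, lapply(results, function(r)
      cbind(r$data, axis = r$axis)))
    gg <- ggplot2::ggplot(pd, ggplot2::aes(x = x, y = y,
                                           label = species)) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           colour = "grey50") +
      ggplot2::geom_point() +
      ggplot2::geom_text(vjust = -0.6, size = 2.8) +
      ggplot2::facet_wrap(~axis, scales = "free_y") +
      ggplot2::labs(x = "maximum thermal tolerance range (deg C)",
                    y = "log range size")
    png_path <- file.path(dir, "association_plot.png")
    grDevices::png(png_path, width = 1400, height = 700, res = 150)
    print(gg)
    grDevices::dev.off()
    paths <- c(paths, png_path)
  }
  invisible(paths)
}
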