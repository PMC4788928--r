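#' Compute the interval report for one dataset (config-driven)
#'
#' Workhorse behind the command-line `compute` subcommand: reads the input
#' (CSV path or the built-in FEV1 fixture), computes the requested intervals
#' and returns the report table. All randomness (bootstrap) flows from
#' `seed`.
#'
#' @param config A list with elements `input` (CSV path) or
#'   `fixture = "table1"`, `methods` (character vector or comma-separated
#'   string), `alpha`, `boot` (G), `seed`, optional `equiv_margin`, optional
#'   variant switches (`t5_df`, `t4_weights`, `corr_variant`,
#'   `hybrid_center`, `marginal_ss`, `gee_working`).
#' @return The [mdiff()] fit (invisibly carries the table via
#'   `as.data.frame`).
#' @export
run_compute <- function(config) {
  cf <- config
  x <- if (!is.null(cf$fixture)) {
    if (!identical(cf$fixture, "table1"))
      stop("unknown fixture: ", cf$fixture, call. = FALSE)
    fev1_formoterol()
  } else if (!is.null(cf$input)) {
    read_incomplete_pairs(cf$input)
  } else stop("config needs 'input' or 'fixture'", call. = FALSE)
  methods <- cf$methods %||%
    c("t1", "t2", "t3", "t4", "t5", "tg", "ws", "wa", "b1", "b2", "b3", "b4")
  if (length(methods) == 1L && grepl(",", methods))
    methods <- strsplit(methods, ",")[[1L]]
  control <- do.call(mdiff_control, cf[intersect(names(cf),
    c("t5_df", "t4_weights", "corr_variant", "hybrid_center",
      "marginal_ss", "gee_working"))])
  mdiff(x, methods = methods, alpha = cf$alpha %||% 0.05,
        G = cf$boot %||% 5000L, seed = cf$seed,
        equiv_margin = cf$equiv_margin, control = control)
}

#' Run a simulation grid from a config (config-driven)
#'
#' Workhorse behind the command-line `simulate` subcommand. The config holds
#' one or more scenarios (fields of [sim_scenario()]), the method tags, and
#' a seed; results are returned as the long table of [run_grid()] and
#' optionally written to CSV.
#'
#' @param config A list with `scenarios` (a list of scenario-field lists, or
#'   a single one), `methods`, `seed`, optional `reps` / `boot` overriding
#'   every scenario's `M` / `G`, optional `out` (CSV path).
#' @return The long results data frame, invisibly when written to `out`.
#' @export
run_simulate <- function(config) {
  cf <- config
  scl <- cf$scenarios
  if (!is.null(scl$family) || !is.null(scl$n)) scl <- list(scl)
  scenarios <- lapply(scl, function(s) {
    if (!is.null(cf$reps)) s$M <- cf$reps
    if (!is.null(cf$boot)) s$G <- cf$boot
    do.call(sim_scenario, s)
  })
  methods <- cf$methods %||% c("t1", "t2", "t5")
  if (length(methods) == 1L && grepl(",", methods))
    methods <- strsplit(methods, ",")[[1L]]
  grid <- run_grid(scenarios, methods, seed = cf$seed %||% 1L)
  if (!is.null(cf$out)) {
    utils::write.csv(grid, cf$out, row.names = FALSE)
    return(invisible(grid))
  }
  grid
}

#' Read a JSON or YAML config file
#'
#' @param path File path; `.json` is parsed with jsonlite, `.yaml`/`.yml`
#'   with the yaml package when available.
#' @return A list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the 'yaml' package; use JSON instead",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

#' Serialise an interval report
#'
#' @param fit An [mdiff()] object.
#' @param format `"text"`, `"csv"` or `"json"`.
#' @param path Optional output path; when `NULL` the text is returned.
#' @return The formatted report, invisibly when written to `path`.
#' @export
format_report <- function(fit, format = c("text", "csv", "json"),
                          path = NULL) {
  format <- match.arg(format)
  df <- as.data.frame(fit)
  out <- switch(format,
    text = paste(utils::capture.output(print(fit)), collapse = "\n"),
    csv  = paste(utils::capture.output(
      utils::write.csv(df, stdout(), row.names = FALSE)), collapse = "\n"),
    json = as.character(jsonlite::toJSON(df, dataframe = "rows",
                                         digits = NA, auto_unbox = TRUE)))
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
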