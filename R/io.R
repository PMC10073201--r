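#' Read a bioluminescence recording from CSV
#'
#' Expects a header with a `time_h` column plus at least one region column,
#' a uniform time grid, and no run of more than 3 consecutive missing
#' values in any region.
#'
#' @param path CSV file path.
#' @return A tibble with `time_h` and the region columns, names preserved.
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_h" %in% names(df)) {
    stop("recording file must have a `time_h` column", call. = FALSE)
  }
  if (ncol(df) < 2L) {
    stop("recording file must have at least one region column", call. = FALSE)
  }
  t <- df$time_h
  dts <- diff(t)
  if (length(dts) && (any(dts <= 0) ||
                      any(abs(dts - dts[1]) > 1e-6 * max(abs(dts[1]), 1)))) {
    stop("`time_h` must be a strictly increasing uniform grid", call. = FALSE)
  }
  for (rg in setdiff(names(df), "time_h")) {
    na_runs <- rle(is.na(df[[rg]]))
    if (any(na_runs$values & na_runs$lengths > 3L)) {
      stop(sprintf("region `%s` has a run of more than 3 missing values", rg),
           call. = FALSE)
    }
  }
  tibble::as_tibble(df)
}

#' @rdname read_recording
#' @param rec recording tibble (`time_h` plus region columns).
#' @export
write_recording <- function(rec, path) {
  utils::write.csv(rec, path, row.names = FALSE)
  invisible(path)
}

#' Read and write model parameter files
#'
#' Parameters are stored as flat JSON with keys `tau_a`, `tau_n`, `tau_v`,
#' `K_an`, `K_na`, `K_av`, `K_va`, `K_nv`, `K_vn`, `gamma`, and an optional
#' `schedule` object with keys `s0_n`, `c_n`, `s0_v`, `c_v`.
#'
#' @param path JSON file path.
#' @return `read_params()`: a list with `params` (an [osc_params()]) and
#'   `schedule` (a [coupling_schedule()] or `NULL`).
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("tau_a", "tau_n", "tau_v", "K_an", "K_na", "K_av", "K_va", "gamma")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("parameter file missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- osc_params(tau_a = x$tau_a, tau_n = x$tau_n, tau_v = x$tau_v,
                  K_an = x$K_an, K_na = x$K_na,
                  K_av = x$K_av, K_va = x$K_va,
                  K_nv = x$K_nv %||% 0, K_vn = x$K_vn %||% 0,
                  gamma = x$gamma)
  sch <- NULL
  if (!is.null(x$schedule)) {
    sch <- coupling_schedule(x$schedule$s0_n %||% 1, x$schedule$c_n %||% 0,
                             x$schedule$s0_v %||% 1, x$schedule$c_v %||% 0)
  }
  list(params = p, schedule = sch)
}

#' @rdname read_params
#' @param params an [osc_params()] object.
#' @param schedule optional [coupling_schedule()].
#' @export
write_params <- function(params, path, schedule = NULL) {
  x <- unclass(params)
  if (!is.null(schedule)) x$schedule <- unclass(schedule)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fitted network parameters shipped with the package
#'
#' The mean fitted parameter set of the DVC three-oscillator network:
#' intrinsic periods 25.7 h (AP), 22.5 h (NTS) and 23.4 h (4Vep), attractive
#' reciprocal AP-NTS coupling with a 0.770 rad phase lag, repulsive AP-4Vep
#' coupling, and no direct NTS-4Vep interaction.
#'
#' @return An [osc_params()] object.
#' @export
#' @examples
#' default_params()
default_params <- function() {
  path <- system.file("extdata", "dvc_params.json", package = "dvcphase",
                      mustWork = TRUE)
  read_params(path)$params
}
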