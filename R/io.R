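#' Read a sweep set from disk
#'
#' Two on-disk layouts are supported.
#'
#' \describe{
#' \item{CSV}{First column `time_ms`; remaining columns named
#'   `"{condition}_{V}mV_r{repeat}"` (e.g. `AIP_-70mV_r1`; current-clamp
#'   sweeps use `cc` in place of `{V}mV`). Header row mandatory, UTF-8,
#'   `.` decimal. Optional leading comment lines `# key: value` carry
#'   metadata (`junction_corrected`). Values survive a round trip to at
#'   least 9 significant digits.}
#' \item{HDF5}{Datasets `/sweeps/{condition}/{V_mV}/{repeat}` (1-D float64),
#'   root attributes `dt_ms`, `t0_ms`, `units_current`, `units_voltage`,
#'   `junction_corrected`. Round trips are bit exact.}
#' }
#'
#' Stored voltages are assumed already corrected for the liquid-junction
#' potential; the `junction_corrected` flag records this and no arithmetic
#' is applied.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"hdf5"`.
#' @return An [ei_sweepset()] (one condition per file; multi-condition files
#'   return a named list of sweep sets).
#' @export
read_sweepset <- function(path, format = c("auto", "csv", "hdf5")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5"
              else "csv"
  if (format == "csv") read_sweepset_csv(path) else read_sweepset_h5(path)
}

#' Write a sweep set to disk
#'
#' @param ss an [ei_sweepset()].
#' @param path output file path.
#' @param format see [read_sweepset()].
#' @param junction_corrected metadata flag stored with the file.
#' @return `path`, invisibly.
#' @export
write_sweepset <- function(ss, path, format = c("auto", "csv", "hdf5"),
                           junction_corrected = TRUE) {
  stopifnot(inherits(ss, "ei_sweepset"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5"
              else "csv"
  if (format == "csv") write_sweepset_csv(ss, path, junction_corrected)
  else write_sweepset_h5(ss, path, junction_corrected)
  invisible(path)
}

sweep_col_name <- function(s) {
  v <- if (is.na(s$holding_potential_mV)) "cc"
       else sprintf("%gmV", s$holding_potential_mV)
  sprintf("%s_%s_r%d", s$condition, v, s$repeat_index)
}

parse_col_name <- function(nm) {
  m <- regmatches(nm, regexec("^([A-Z]+)_(-?[0-9.]+mV|cc)_r([0-9]+)$", nm))[[1]]
  if (length(m) == 0L)
    stop(sprintf("column '%s' does not match '{condition}_{V}mV_r{repeat}'",
                 nm), call. = FALSE)
  v <- if (m[3] == "cc") NA_real_ else as.numeric(sub("mV$", "", m[3]))
  list(condition = m[2], holding_potential_mV = v,
       repeat_index = as.integer(m[4]))
}

write_sweepset_csv <- function(ss, path, junction_corrected) {
  cols <- lapply(ss$sweeps, function(s) s$values)
  names(cols) <- vapply(ss$sweeps, sweep_col_name, character(1))
  df <- data.frame(time_ms = tb_times(ss$timebase), cols, check.names = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# junction_corrected: %s",
                     tolower(as.character(junction_corrected))), con)
  writeLines(paste(names(df), collapse = ","), con)
  body <- do.call(paste, c(lapply(df, formatC, digits = 10, format = "g"),
                           sep = ","))
  writeLines(body, con)
}

read_sweepset_csv <- function(path) {
  first <- readLines(path, n = 50L)
  skip <- sum(cumprod(startsWith(first, "#")))
  df <- utils::read.csv(path, skip = skip, check.names = FALSE,
                        colClasses = "numeric")
  if (ncol(df) < 2L || names(df)[1] != "time_ms")
    stop("sweep CSV must have a 'time_ms' first column and >= 1 sweep column",
         call. = FALSE)
  t <- df[[1]]
  dt <- diff(t)
  if (any(!is.finite(dt)) || diff(range(dt)) > 1e-6 * dt[1])
    stop("'time_ms' column is not a uniform grid", call. = FALSE)
  tb <- timebase(t[1], mean(dt), length(t))
  sweeps <- lapply(names(df)[-1], function(nm) {
    meta <- parse_col_name(nm)
    ei_sweep(df[[nm]], tb, meta$holding_potential_mV, meta$condition,
             meta$repeat_index,
             units = if (is.na(meta$holding_potential_mV)) "mV" else "pA")
  })
  split_conditions(sweeps)
}

split_conditions <- function(sweeps) {
  conds <- vapply(sweeps, function(s) s$condition, character(1))
  out <- lapply(split(sweeps, conds), function(sw) {
    ## canonical order: holding potential, then repeat
    hp <- vapply(sw, function(s) s$holding_potential_mV, numeric(1))
    rp <- vapply(sw, function(s) s$repeat_index, integer(1))
    ei_sweepset(sw[order(hp, rp, na.last = TRUE)])
  })
  if (length(out) == 1L) out[[1]] else out
}

write_sweepset_h5 <- function(ss, path, junction_corrected) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(ss$timebase$dt_ms, fid, "dt_ms")
  rhdf5::h5writeAttribute(ss$timebase$t0_ms, fid, "t0_ms")
  rhdf5::h5writeAttribute("pA", fid, "units_current")
  rhdf5::h5writeAttribute("mV", fid, "units_voltage")
  rhdf5::h5writeAttribute(as.integer(junction_corrected), fid,
                          "junction_corrected")
  rhdf5::H5Fclose(fid)
  rhdf5::h5createGroup(path, "sweeps")
  made <- character(0)
  for (s in ss$sweeps) {
    g1 <- paste0("sweeps/", s$condition)
    vgrp <- if (is.na(s$holding_potential_mV)) "cc"
            else sprintf("%g", s$holding_potential_mV)
    g2 <- paste0(g1, "/", vgrp)
    for (g in c(g1, g2)) if (!g %in% made) {
      rhdf5::h5createGroup(path, g)
      made <- c(made, g)
    }
    rhdf5::h5write(s$values, path, paste0(g2, "/", s$repeat_index))
  }
}

read_sweepset_h5 <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  attrs <- rhdf5::h5readAttributes(path, "/")
  for (k in c("dt_ms", "t0_ms"))
    if (is.null(attrs[[k]]))
      stop(sprintf("HDF5 file lacks required root attribute '%s'", k),
           call. = FALSE)
  ls <- rhdf5::h5ls(path)
  ds <- ls[ls$otype == "H5I_DATASET" & grepl("^/sweeps", ls$group), ,
           drop = FALSE]
  if (nrow(ds) == 0L) stop("no datasets under /sweeps", call. = FALSE)
  sweeps <- vector("list", nrow(ds))
  tb <- NULL
  for (i in seq_len(nrow(ds))) {
    parts <- strsplit(sub("^/", "", ds$group[i]), "/")[[1]]  # sweeps cond V
    vals <- as.numeric(rhdf5::h5read(path, paste0(ds$group[i], "/",
                                                  ds$name[i])))
    if (is.null(tb)) tb <- timebase(as.numeric(attrs$t0_ms),
                                    as.numeric(attrs$dt_ms), length(vals))
    if (length(vals) != tb$n_samples)
      stop("sweeps in file have inconsistent lengths", call. = FALSE)
    v <- if (parts[3] == "cc") NA_real_ else as.numeric(parts[3])
    sweeps[[i]] <- ei_sweep(vals, tb, v, parts[2],
                            as.integer(ds$name[i]),
                            units = if (is.na(v)) "mV" else "pA")
  }
  split_conditions(sweeps)
}
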