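# File-format dialects: motion TSV, landmark TSV, cohort CSV, flat
# key-value config, and the plain-text + CSV report. Every file written
# carries a header comment with package version, config hash and seed, so
# runs are traceable; readers skip '#' lines.

pl_version <- function() as.character(utils::packageVersion("pitchload"))

# small deterministic string hash (hex) for config/input digests
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

file_digest <- function(path) fnv1a(readLines(path, warn = FALSE))

output_header <- function(kind, seed = NA, config = NULL) {
  cfg_hash <- if (is.null(config)) "none" else
    fnv1a(paste(names(config), vapply(config, function(v) paste(format(v), collapse = ","), ""), sep = "="))
  sprintf("# pitchload %s %s; seed=%s; config_hash=%s",
          pl_version(), kind, as.character(seed), cfg_hash)
}

#' Write a motion recording as TSV
#'
#' One row per frame: first column `time` (s), then per sensor the columns
#' `<sensor>.x .y .z` (m, world) and `<sensor>.qw .qx .qy .qz` (unit
#' quaternion). Values carry 9 significant digits, so a write-read
#' round-trip reproduces the recording to those digits exactly. Header
#' comments store the frame rate and handedness.
#'
#' @param recording a [motion_recording()].
#' @param path output path.
#' @param seed,config optional provenance recorded in the header.
#' @export
write_motion_tsv <- function(recording, path, seed = NA, config = NULL) {
  stopifnot(inherits(recording, "motion_recording"))
  n <- n_frames(recording)
  cols <- list(time = recording$time)
  for (lab in names(recording$sensors)) {
    s <- recording$sensors[[lab]]
    for (i in 1:3) cols[[paste0(lab, ".", c("x", "y", "z")[i])]] <- s$pos[, i]
    for (i in 1:4) cols[[paste0(lab, ".", c("qw", "qx", "qy", "qz")[i])]] <- s$quat[, i]
  }
  df <- as.data.frame(cols, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(output_header("motion", seed, config),
               paste0("# fs=", format(recording$fs, digits = 9)),
               paste0("# handedness=", recording$handedness)), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  body <- apply(df, 1, function(r) paste(formatC(as.numeric(r), digits = 9, format = "g"),
                                         collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read a motion recording from TSV
#'
#' Inverse of [write_motion_tsv()]. Quaternions within 1e-6 of unit norm
#' are renormalized; larger deviations, ragged rows, non-monotonic time or
#' missing sensor columns are rejected with the offending line number.
#'
#' @param path input path.
#' @return a [motion_recording()].
#' @export
read_motion_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty motion file: ", path)
  meta <- grep("^#", lines, value = TRUE)
  fs <- as.numeric(sub("^# fs=", "", grep("^# fs=", meta, value = TRUE)[1]))
  handed <- sub("^# handedness=", "", grep("^# handedness=", meta, value = TRUE)[1])
  if (!is.finite(fs)) stop("motion file lacks '# fs=' header: ", path)
  if (!handed %in% c("R", "L")) stop("motion file lacks '# handedness=' header: ", path)
  keep <- !grepl("^#", lines)
  first_data_line <- which(keep)[1]
  body <- lines[keep]
  if (length(body) < 2L) stop("motion file has no data rows: ", path)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  ncol_expect <- length(header)
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  lens <- lengths(rows)
  if (any(lens != ncol_expect)) {
    bad <- which(lens != ncol_expect)[1]
    stop("ragged row in ", path, " at line ", first_data_line + bad,
         ": expected ", ncol_expect, " fields, found ", lens[bad])
  }
  M <- matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
  colnames(M) <- header
  if (anyNA(M)) stop("non-numeric field in motion file ", path)
  if (header[1] != "time") stop("first column must be 'time'")
  time <- M[, 1]
  bad_t <- which(diff(time) <= 0)
  if (length(bad_t))
    stop("non-monotonic time in ", path, " at line ", first_data_line + bad_t[1] + 1L)
  sensor_names <- unique(sub("\\.[^.]+$", "", header[-1]))
  sensors <- list()
  for (lab in sensor_names) {
    want <- paste0(lab, ".", c("x", "y", "z", "qw", "qx", "qy", "qz"))
    if (!all(want %in% header))
      stop("sensor '", lab, "' is missing columns: ",
           paste(setdiff(want, header), collapse = ", "))
    q <- M[, want[4:7], drop = FALSE]
    qn <- sqrt(rowSums(q^2))
    off <- which(abs(qn - 1) > 1e-6)
    if (length(off))
      stop("sensor '", lab, "' quaternion departs from unit norm by ",
           format(max(abs(qn - 1)), digits = 3), " at line ",
           first_data_line + off[which.max(abs(qn - 1)[off])] + 1L)
    sensors[[lab]] <- list(pos = unname(M[, want[1:3], drop = FALSE]),
                           quat = unname(q / qn))
  }
  motion_recording(fs, sensors, handedness = handed, time = time)
}

#' Write / read a landmark map (TSV: landmark, sensor, ox, oy, oz)
#'
#' @param map a [landmark_map()].
#' @param path file path.
#' @rdname landmark_io
#' @export
write_landmarks_tsv <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header("landmarks"), con)
  utils::write.table(as.data.frame(map), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname landmark_io
#' @export
read_landmarks_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  landmark_map(df)
}

#' Write a cohort table as CSV
#'
#' @param cohort a `cohort_table`.
#' @param path file path.
#' @param seed,config optional provenance recorded in the header comment.
#' @export
write_cohort_csv <- function(cohort, path, seed = NA, config = NULL) {
  cohort <- as_cohort_table(as.data.frame(cohort))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header("cohort", seed, config), con)
  utils::write.csv(as.data.frame(cohort), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Expects the documented header (`id`, `paf_n`, `ppf_n`, `pain`, plus
#' optional demographics); `pain` may be coded 0/1 or yes/no. Duplicate
#' ids, non-numeric kinetics and empty files are rejected.
#'
#' @param path file path.
#' @return a `cohort_table` data.frame.
#' @export
read_cohort_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  if (!length(lines) || all(!nzchar(lines))) stop("empty cohort file: ", path)
  df <- utils::read.csv(text = paste(lines, collapse = "\n"), stringsAsFactors = FALSE)
  if (!nrow(df)) stop("cohort file has a header but no rows: ", path)
  need <- c("id", "paf_n", "ppf_n", "pain")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("cohort file missing columns: ", paste(missing, collapse = ", "))
  if (is.character(df$pain)) {
    low <- tolower(trimws(df$pain))
    df$pain <- ifelse(low %in% c("yes", "y", "1"), 1L,
                      ifelse(low %in% c("no", "n", "0"), 0L, NA_integer_))
  }
  if (anyNA(df$pain)) stop("unreadable pain coding in ", path)
  for (cl in c("paf_n", "ppf_n")) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (anyNA(v)) stop("non-numeric values in column '", cl, "' of ", path)
    df[[cl]] <- v
  }
  as_cohort_table(df)
}

#' Write the association report
#'
#' Emits `report.txt` (the printed report) plus CSV tables
#' (`descriptives.csv`, `correlations.csv`, `logistic.csv`,
#' `classification.csv`) into a directory.
#'
#' @param assoc a `pain_association` from [run_association()].
#' @param dir output directory (created if needed).
#' @param seed,config optional provenance for the headers.
#' @return invisibly, the paths written.
#' @export
write_report <- function(assoc, dir, seed = NA, config = NULL) {
  stopifnot(inherits(assoc, "pain_association"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  txt <- file.path(dir, "report.txt")
  writeLines(c(output_header("report", seed, config),
               utils::capture.output(print(assoc))), txt)
  paths <- c(paths, txt)
  wcsv <- function(df, name) {
    p <- file.path(dir, name)
    con <- file(p, "w")
    writeLines(output_header(sub(".csv$", "", name), seed, config), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    paths <<- c(paths, p)
  }
  wcsv(cbind(parameter = rownames(assoc$descriptives), assoc$descriptives),
       "descriptives.csv")
  wcsv(do.call(rbind, lapply(assoc$correlations, function(cr)
    data.frame(pair = cr$label, r = cr$r, t = cr$t, df = cr$df, p = cr$p))),
    "correlations.csv")
  if (!is.null(assoc$fit)) {
    s <- summary(assoc$fit)
    wcsv(cbind(term = rownames(s$table), s$table,
               ci_lower = c(NA, assoc$fit$or_ci[1]),
               ci_upper = c(NA, assoc$fit$or_ci[2])), "logistic.csv")
    cl <- assoc$classification
    wcsv(data.frame(tp = cl$tp, tn = cl$tn, fp = cl$fp, fn = cl$fn,
                    overall_pct = cl$overall_pct, pain_pct = cl$pain_pct,
                    nopain_pct = cl$nopain_pct, threshold = cl$threshold),
         "classification.csv")
  }
  invisible(paths)
}

#' Read / write a flat key-value configuration file
#'
#' Lines of the form `key = value`; '#' comments allowed. Values are
#' coerced numerically where possible and merged over the defaults of
#' [pipeline_config()]; command-line flags override file values.
#'
#' @param path config file path.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad)) stop("malformed config line ", bad[1], " in ", path)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  args <- list()
  for (i in seq_along(keys)) {
    num <- suppressWarnings(as.numeric(vals[i]))
    args[[keys[i]]] <- if (is.na(num)) vals[i] else num
  }
  unknown <- setdiff(names(args), names(formals(pipeline_config)))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, args)
}
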