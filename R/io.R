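#' Read a keypoint CSV file
#'
#' Reads the capture app's per-measurement CSV dialect: one row per frame, a
#' `frame` column (0-based, contiguous), then for every keypoint the columns
#' `<name>_x`, `<name>_y`, `<name>_z`, `<name>_conf`, optionally carrying a
#' `_raw` / `_smooth` suffix when the file stores both channels. Empty
#' coordinate cells denote masked (excluded) entries. Unknown extra columns
#' are preserved as metadata.
#'
#' @param path File path.
#' @param variant `"auto"` (default: prefer the smoothed channel, fall back
#'   to raw, then to unsuffixed columns), `"smoothed"` or `"raw"`.
#' @param fps Frames per second used to derive timestamps (default 30).
#' @param measurement_id,subject_id,group Metadata attached to the series;
#'   default ids are derived from the file name.
#'
#' @return A [keypoint_series()].
#' @export
read_keypoint_csv <- function(path, variant = c("auto", "smoothed", "raw"),
                              fps = 30,
                              measurement_id = NULL, subject_id = "s1",
                              group = "unknown") {
  variant <- match.arg(variant)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  measurement_id <- measurement_id %||% sub("\\.csv$", "", basename(path))

  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!"frame" %in% names(df)) {
    stop("schema error: missing required column 'frame'", call. = FALSE)
  }

  pat <- "^(.+)_(x|y|z|conf)(_raw|_smooth)?$"
  kcols <- grep(pat, names(df), value = TRUE)
  info <- data.frame(
    col = kcols,
    keypoint = sub(pat, "\\1", kcols),
    field = sub(pat, "\\2", kcols),
    suffix = sub(pat, "\\3", kcols),
    stringsAsFactors = FALSE
  )

  pick_suffix <- function(want) {
    has <- unique(info$suffix)
    if (want == "auto") {
      if ("_smooth" %in% has) "_smooth"
      else if ("_raw" %in% has) "_raw"
      else ""
    } else {
      sfx <- if (want == "smoothed") "_smooth" else "_raw"
      if (sfx %in% has) sfx
      else if ("" %in% has) ""
      else stop("schema error: no columns for variant '", want, "'",
                call. = FALSE)
    }
  }
  sfx <- pick_suffix(variant)
  sel <- info[info$suffix == sfx, ]
  kp <- unique(sel$keypoint)

  missing_req <- setdiff(pipeline_keypoints(), kp)
  if (length(missing_req) > 0) {
    stop("schema error: missing required keypoint columns for: ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  need <- as.vector(t(outer(kp, c("x", "y", "z", "conf"),
                            function(k, f) paste0(k, "_", f, sfx))))
  absent <- setdiff(need, sel$col)
  if (length(absent) > 0) {
    stop("schema error: missing columns: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }

  parse_num <- function(col, allow_empty) {
    raw <- df[[col]]
    out <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(out))
    if (length(bad) > 0) {
      stop("parse error: non-numeric value '", raw[bad[1]], "' in column '",
           col, "', data row ", bad[1], call. = FALSE)
    }
    if (!allow_empty && anyNA(out)) {
      stop("parse error: empty value in column '", col, "', data row ",
           which(is.na(out))[1], call. = FALSE)
    }
    out
  }

  frame <- parse_num("frame", allow_empty = FALSE)
  if (!identical(as.numeric(frame), as.numeric(seq_along(frame) - 1))) {
    stop("frame indices must be contiguous starting at 0", call. = FALSE)
  }
  n <- length(frame)

  coords <- array(NA_real_, c(n, length(kp), 3),
                  dimnames = list(NULL, kp, c("x", "y", "z")))
  conf <- matrix(1, n, length(kp), dimnames = list(NULL, kp))
  for (k in kp) {
    coords[, k, 1] <- parse_num(paste0(k, "_x", sfx), TRUE)
    coords[, k, 2] <- parse_num(paste0(k, "_y", sfx), TRUE)
    coords[, k, 3] <- parse_num(paste0(k, "_z", sfx), TRUE)
    cc <- parse_num(paste0(k, "_conf", sfx), TRUE)
    conf[, k] <- ifelse(is.na(cc), 1, cc)
  }
  mask <- is.na(coords[, , 1]) | is.na(coords[, , 2]) | is.na(coords[, , 3])
  dim(mask) <- c(n, length(kp))
  dimnames(mask) <- list(NULL, kp)

  extra_cols <- setdiff(names(df), c("frame", kcols))
  extra <- if (length(extra_cols) > 0) {
    tibble::as_tibble(df[extra_cols])
  } else NULL

  out_variant <- if (sfx == "_raw") "raw"
                 else if (sfx == "_smooth") "smoothed"
                 else if (variant == "raw") "raw" else "smoothed"
  keypoint_series(coords, conf, mask, fps = fps,
                  measurement_id = measurement_id, subject_id = subject_id,
                  group = group, variant = out_variant, extra = extra)
}

#' Write a keypoint series to CSV
#'
#' Emits the dialect read by [read_keypoint_csv()]. Column names carry the
#' series' variant suffix (`_smooth` or `_raw`); coordinates of masked
#' entries are written as empty cells (their confidence is kept). The file
#' round-trips: reading it back yields a series equal to the input (bit-equal
#' unmasked coordinates).
#'
#' @param series A [keypoint_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_keypoint_csv <- function(series, path) {
  stopifnot(inherits(series, "keypoint_series"))
  sfx <- if (series$variant == "raw") "_raw" else "_smooth"
  n <- n_frames(series)
  out <- list(frame = seq_len(n) - 1L)
  for (k in series$keypoints) {
    masked <- series$mask[, k]
    for (d in 1:3) {
      v <- series$coords[, k, d]
      v[masked] <- NA_real_
      out[[paste0(k, "_", c("x", "y", "z")[d], sfx)]] <- v
    }
    out[[paste0(k, "_conf", sfx)]] <- series$confidence[, k]
  }
  df <- tibble::as_tibble(out)
  if (!is.null(series$extra)) df <- dplyr::bind_cols(df, series$extra)
  readr::write_csv(df, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a cohort table
#'
#' One row per measurement: `subject_id,group,sex,age,measurement_id`.
#'
#' @param path CSV path.
#' @return A list with `cohort` (one row per subject: subject_id, group, sex,
#'   age) and `measurements` (one row per measurement).
#' @export
read_cohort_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    subject_id = "c", group = "c", sex = "c", age = "d",
    measurement_id = "c"
  ), progress = FALSE)
  cohort <- dplyr::distinct(df, .data$subject_id, .data$group, .data$sex,
                            .data$age)
  list(cohort = cohort,
       measurements = df[, c("measurement_id", "subject_id")])
}

#' Summarize a cohort
#'
#' Per-group participant counts, sex ratios, age mean, SD and range, and
#' measurement counts, plus an `"all"` row with the total participant count
#' and the average number of measurements per person (one decimal).
#'
#' @param cohort Tibble with one row per subject: `subject_id`, `group`,
#'   optionally `sex` (`"M"`/`"F"`/`NA`) and `age`.
#' @param measurements Tibble with one row per measurement: `measurement_id`,
#'   `subject_id`.
#' @return A tibble with one row per group plus the `"all"` row.
#' @export
cohort_summary <- function(cohort, measurements) {
  stopifnot(all(c("subject_id", "group") %in% names(cohort)))
  if (anyDuplicated(cohort$subject_id) > 0) {
    stop("cohort must have one row per subject", call. = FALSE)
  }
  unknown <- setdiff(measurements$subject_id, cohort$subject_id)
  if (length(unknown) > 0) {
    stop("consistency error: measurements reference unknown subjects: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  if (!"sex" %in% names(cohort)) cohort$sex <- NA_character_
  if (!"age" %in% names(cohort)) cohort$age <- NA_real_

  n_meas <- table(factor(measurements$subject_id,
                         levels = cohort$subject_id))
  cohort$n_measurements <- as.integer(n_meas[cohort$subject_id])

  one <- function(df, label) {
    tibble::tibble(
      group = label,
      n_subjects = nrow(df),
      n_male = sum(df$sex == "M", na.rm = TRUE),
      n_female = sum(df$sex == "F", na.rm = TRUE),
      n_sex_unknown = sum(is.na(df$sex)),
      age_mean = mean(df$age, na.rm = TRUE),
      age_sd = stats::sd(df$age, na.rm = TRUE),
      age_min = suppressWarnings(min(df$age, na.rm = TRUE)),
      age_max = suppressWarnings(max(df$age, na.rm = TRUE)),
      n_measurements = sum(df$n_measurements),
      measurements_per_person =
        round(sum(df$n_measurements) / nrow(df), 1)
    )
  }
  groups <- unique(cohort$group)
  by_group <- dplyr::bind_rows(lapply(groups, function(g) {
    one(cohort[cohort$group == g, ], g)
  }))
  dplyr::bind_rows(by_group, one(cohort, "all"))
}
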