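#' Construct a bout stream for one animal
#'
#' A bout stream is the raw unit of analysis: a time-ordered sequence of
#' feeding bouts (one row per feeder visit, with start time, duration and
#' mass of food removed) plus the recording window they were observed in.
#'
#' @param bouts A data frame with columns `t_start` (`POSIXct`),
#'   `duration_s` (seconds, >= 0) and `mass_g` (grams, >= 0). Rows are
#'   sorted by `t_start`; input order does not matter.
#' @param animal_id Identifier of the animal the stream belongs to.
#' @param window Length-2 `POSIXct` recording window. Defaults to the span
#'   of the bouts themselves. Every bout must lie inside it.
#' @return An object of class `bout_stream`: a list with elements
#'   `animal_id`, `bouts` (a tibble) and `window`.
#' @export
bout_stream <- function(bouts, animal_id, window = NULL) {
  bouts <- tibble::as_tibble(bouts)
  req <- c("t_start", "duration_s", "mass_g")
  missing_cols <- setdiff(req, names(bouts))
  if (length(missing_cols))
    stop("bouts are missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(bouts) && !inherits(bouts$t_start, "POSIXct"))
    stop("`t_start` must be POSIXct.", call. = FALSE)
  bouts <- bouts[order(bouts$t_start), req, drop = FALSE]
  if (anyNA(bouts))
    stop("bouts contain missing values.", call. = FALSE)
  bad_mass <- which(bouts$mass_g < 0)
  if (length(bad_mass))
    stop("negative bout mass at row(s) ", paste(bad_mass, collapse = ", "),
         " (after sorting) for animal ", animal_id, call. = FALSE)
  if (any(bouts$duration_s < 0))
    stop("negative bout duration for animal ", animal_id, call. = FALSE)
  if (nrow(bouts) > 1) {
    dup <- which(duplicated(as.numeric(bouts$t_start)))
    if (length(dup))
      stop("duplicate bout timestamps for animal ", animal_id, " at sorted row(s) ",
           paste(dup, collapse = ", "), call. = FALSE)
    t_end <- as.numeric(bouts$t_start) + bouts$duration_s
    overlap <- which(as.numeric(bouts$t_start[-1]) < t_end[-nrow(bouts)] - 1e-9)
    if (length(overlap))
      stop("overlapping bouts for animal ", animal_id, ": bout(s) ",
           paste(overlap + 1, collapse = ", "), " start before the previous bout ends.",
           call. = FALSE)
  }
  if (is.null(window)) {
    window <- if (nrow(bouts)) {
      c(min(bouts$t_start),
        max(bouts$t_start + bouts$duration_s))
    } else {
      as.POSIXct(c(NA, NA))
    }
  }
  window <- as.POSIXct(window)
  if (length(window) != 2)
    stop("`window` must be a length-2 POSIXct (start, end).", call. = FALSE)
  if (nrow(bouts) && !anyNA(window)) {
    if (window[2] <= window[1])
      stop("recording window end must be after its start.", call. = FALSE)
    t_end <- bouts$t_start + bouts$duration_s
    if (any(bouts$t_start < window[1] - 1e-9) || any(t_end > window[2] + 1e-9))
      stop("bouts fall outside the recording window for animal ", animal_id,
           call. = FALSE)
  }
  structure(list(animal_id = as.character(animal_id),
                 bouts = bouts, window = window),
            class = "bout_stream")
}

#' @export
print.bout_stream <- function(x, ...) {
  cat(sprintf("<bout_stream> animal %s: %d bouts, %.3f g total",
              x$animal_id, nrow(x$bouts), sum(x$bouts$mass_g)))
  if (!anyNA(x$window))
    cat(sprintf(", window %s .. %s",
                format(x$window[1], "%Y-%m-%d %H:%M"),
                format(x$window[2], "%Y-%m-%d %H:%M")))
  cat("\n")
  invisible(x)
}

parse_timestamps <- function(x, tz = "UTC") {
  as.POSIXct(as.character(x), tz = tz,
             tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"),
             optional = TRUE)
}

#' Read a bout-level event log
#'
#' Reads a delimited text log with one row per feeding bout and returns one
#' [bout_stream()] per animal. Timestamps must be ISO 8601
#' (`YYYY-MM-DD HH:MM:SS` or with a `T` separator); rows that fail to parse
#' or carry negative masses are reported with their line numbers.
#'
#' @param path Path to a CSV file.
#' @param schema Named character vector remapping the expected logical
#'   columns (`animal_id`, `timestamp`, `bout_duration_s`, `bout_mass_g`)
#'   to the file's actual column names.
#' @param window Optional length-2 `POSIXct` recording window applied to
#'   all animals; defaults to each animal's own bout span.
#' @param tz Time zone used to interpret the (timezone-naive) timestamps.
#' @return A named list of `bout_stream` objects, one per animal.
#' @export
read_bout_log <- function(path,
                          schema = c(animal_id = "animal_id",
                                     timestamp = "timestamp",
                                     bout_duration_s = "bout_duration_s",
                                     bout_mass_g = "bout_mass_g"),
                          window = NULL, tz = "UTC") {
  defaults <- c(animal_id = "animal_id", timestamp = "timestamp",
                bout_duration_s = "bout_duration_s", bout_mass_g = "bout_mass_g")
  defaults[names(schema)] <- schema
  schema <- defaults
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols))
    stop("bout log ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  t <- parse_timestamps(raw[[schema[["timestamp"]]]], tz = tz)
  dur <- suppressWarnings(as.numeric(raw[[schema[["bout_duration_s"]]]]))
  mass <- suppressWarnings(as.numeric(raw[[schema[["bout_mass_g"]]]]))
  # data line numbers: +1 for the header row
  bad <- which(is.na(t) | is.na(dur) | is.na(mass) | mass < 0 | dur < 0)
  if (length(bad))
    stop("malformed row(s) in ", path, " at line(s) ",
         paste(bad + 1, collapse = ", "),
         " (unparseable timestamp, or negative/missing duration or mass).",
         call. = FALSE)
  df <- tibble::tibble(animal_id = as.character(raw[[schema[["animal_id"]]]]),
                       t_start = t, duration_s = dur, mass_g = mass)
  ids <- unique(df$animal_id)
  streams <- lapply(ids, function(id) {
    b <- df[df$animal_id == id, c("t_start", "duration_s", "mass_g")]
    bout_stream(b, animal_id = id, window = window)
  })
  stats::setNames(streams, ids)
}

#' Write a bout log readable by [read_bout_log()]
#'
#' @param streams A `bout_stream` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bout_log <- function(streams, path) {
  if (inherits(streams, "bout_stream")) streams <- list(streams)
  rows <- lapply(streams, function(s) {
    if (!nrow(s$bouts)) return(NULL)
    data.frame(animal_id = s$animal_id,
               timestamp = format(s$bouts$t_start, "%Y-%m-%d %H:%M:%OS6"),
               bout_duration_s = sprintf("%.9g", s$bouts$duration_s),
               bout_mass_g = sprintf("%.9g", s$bouts$mass_g))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an animal record
#'
#' Holds the per-animal metadata (genotype, sex, age) and the body-weight
#' series used to normalize energy intake to body weight.
#'
#' @param animal_id Identifier.
#' @param genotype `"control"` or `"knockout"`.
#' @param sex `"male"` or `"female"`.
#' @param age_weeks Age at the start of recording, weeks.
#' @param body_weight Data frame with columns `timestamp` (`POSIXct`) and
#'   `bw_g` (grams, > 0), sorted by time.
#' @return An object of class `animal_record`.
#' @export
animal_record <- function(animal_id, genotype = c("control", "knockout"),
                          sex = c("male", "female"), age_weeks = NA_real_,
                          body_weight = NULL) {
  genotype <- match.arg(genotype)
  sex <- match.arg(sex)
  if (is.null(body_weight)) {
    body_weight <- tibble::tibble(timestamp = as.POSIXct(character()),
                                  bw_g = numeric())
  }
  body_weight <- tibble::as_tibble(body_weight)
  stopifnot(all(c("timestamp", "bw_g") %in% names(body_weight)))
  if (nrow(body_weight)) {
    if (any(body_weight$bw_g <= 0))
      stop("body weights must be strictly positive (animal ", animal_id, ").",
           call. = FALSE)
    body_weight <- body_weight[order(body_weight$timestamp), ]
  }
  structure(list(animal_id = as.character(animal_id), genotype = genotype,
                 sex = sex, age_weeks = as.numeric(age_weeks),
                 body_weight = body_weight),
            class = "animal_record")
}

#' @export
print.animal_record <- function(x, ...) {
  cat(sprintf("<animal_record> %s: %s %s, %g wk, %d body weights\n",
              x$animal_id, x$genotype, x$sex, x$age_weeks, nrow(x$body_weight)))
  invisible(x)
}

#' Mean body weight inside a time window
#'
#' Arithmetic mean of the body-weight measurements falling inside the
#' window (inclusive of both endpoints); this is the denominator used to
#' express intake per gram of body weight.
#'
#' @param animal An [animal_record()].
#' @param window Length-2 `POSIXct` interval.
#' @return Mean body weight, grams.
#' @export
mean_body_weight <- function(animal, window) {
  stopifnot(inherits(animal, "animal_record"))
  bw <- animal$body_weight
  keep <- bw$timestamp >= window[1] & bw$timestamp <= window[2]
  if (!any(keep))
    stop("no body-weight measurement inside the window for animal ",
         animal$animal_id,
         "; widen the window or supply a single representative weight.",
         call. = FALSE)
  mean(bw$bw_g[keep])
}

#' Read body-weight and metadata tables into animal records
#'
#' `read_body_weights()` expects columns `animal_id, timestamp, bw_g`;
#' `read_metadata()` expects `animal_id, genotype, sex, age_weeks`.
#' `read_animal_records()` joins the two into a named list of
#' [animal_record()] objects.
#'
#' @param path,bw_path,meta_path CSV paths.
#' @param tz Time zone for timestamps.
#' @return A tibble (`read_body_weights`, `read_metadata`) or a named list
#'   of `animal_record` (`read_animal_records`).
#' @export
read_body_weights <- function(path, tz = "UTC") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "timestamp", "bw_g")
  if (!all(req %in% names(raw)))
    stop("body-weight table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  t <- parse_timestamps(raw$timestamp, tz = tz)
  if (anyNA(t))
    stop("unparseable timestamp(s) in ", path, " at line(s) ",
         paste(which(is.na(t)) + 1, collapse = ", "), call. = FALSE)
  tibble::tibble(animal_id = as.character(raw$animal_id),
                 timestamp = t, bw_g = as.numeric(raw$bw_g))
}

#' @rdname read_body_weights
#' @export
read_metadata <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "genotype", "sex", "age_weeks")
  if (!all(req %in% names(raw)))
    stop("metadata table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  tibble::as_tibble(raw[req])
}

#' @rdname read_body_weights
#' @export
read_animal_records <- function(meta_path, bw_path, tz = "UTC") {
  meta <- read_metadata(meta_path)
  bw <- read_body_weights(bw_path, tz = tz)
  recs <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$animal_id[i]
    animal_record(id, genotype = meta$genotype[i], sex = meta$sex[i],
                  age_weeks = meta$age_weeks[i],
                  body_weight = bw[bw$animal_id == id, c("timestamp", "bw_g")])
  })
  stats::setNames(recs, meta$animal_id)
}
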