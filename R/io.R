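#' Read a multichannel recording from disk
#'
#' Supported formats: `"delimited"` (tab-separated matrix, channels in rows,
#' samples in columns, no header) and `"edf"` (European Data Format,
#' 16-bit; continuous recordings with a common sampling rate).  Channels and
#' samples are 0-based in all window arithmetic ([segment_epochs()]);
#' matrices returned here are plain 1-based R matrices.
#'
#' @param path File path.
#' @param format `"delimited"` or `"edf"`.
#' @param fs Sampling rate in Hz; required for delimited input (EDF carries
#'   its own).
#' @return A `sensor_recording` (fields `y_t`, `fs`, `sigma2_n = NA`,
#'   `subject_id`, `trial_id`; channel labels in `attr(,"labels")` for EDF).
#' @export
read_recording <- function(path, format = c("delimited", "edf"), fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "delimited") {
    if (is.null(fs)) stop("fs must be given for delimited input", call. = FALSE)
    y <- as.matrix(read.table(path, sep = "\t", header = FALSE))
    dimnames(y) <- NULL
    structure(list(y_t = y, fs = fs, sigma2_n = NA_real_,
                   subject_id = NA_integer_, trial_id = NA_integer_),
              class = "sensor_recording")
  } else {
    read_edf(path)
  }
}

#' Write a recording as a delimited matrix
#'
#' @param rec A `sensor_recording`.
#' @param path Output path (TSV, channels in rows).
#' @export
write_recording <- function(rec, path) {
  write.table(rec$y_t, path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a recording as minimal EDF
#'
#' Continuous EDF with one data record per second; `fs` must therefore be a
#' positive integer and the sample count a multiple of `fs` (the tail is
#' zero-padded otherwise).  Amplitudes are scaled to the full 16-bit digital
#' range per channel, so the round trip is exact only up to quantization
#' (relative error about 3e-5 of the channel range).
#'
#' @param rec A `sensor_recording` with integer `fs`.
#' @param path Output path.
#' @param labels Optional channel labels (16 ASCII chars max).
#' @export
write_edf <- function(rec, path, labels = NULL) {
  y <- rec$y_t
  fs <- as.integer(rec$fs)
  if (fs <= 0 || rec$fs != fs) stop("EDF export needs integer fs", call. = FALSE)
  nc <- nrow(y)
  n_rec <- ceiling(ncol(y) / fs)
  if (ncol(y) < n_rec * fs)
    y <- cbind(y, matrix(0, nc, n_rec * fs - ncol(y)))
  labels <- labels %||% sprintf("EEG %03d", seq_len(nc))

  pmin_ <- apply(y, 1L, min); pmax_ <- apply(y, 1L, max)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  pad <- function(x, n) {
    s <- substr(format(x), 1L, n)
    sprintf(paste0("%-", n, "s"), s)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(pad("0", 8)); wr(pad("synthetic subject", 80))
  wr(pad("synthetic recording", 80))
  wr(pad("01.01.00", 8)); wr(pad("00.00.00", 8))
  wr(pad(256L * (1L + nc), 8)); wr(pad("", 44))
  wr(pad(n_rec, 8)); wr(pad(1L, 8)); wr(pad(nc, 4))
  for (lab in labels) wr(pad(lab, 16))
  for (i in seq_len(nc)) wr(pad("synthetic", 80))
  for (i in seq_len(nc)) wr(pad("uV", 8))
  for (i in seq_len(nc)) wr(pad(signif(pmin_[i], 7), 8))
  for (i in seq_len(nc)) wr(pad(signif(pmax_[i], 7), 8))
  for (i in seq_len(nc)) wr(pad(dmin, 8))
  for (i in seq_len(nc)) wr(pad(dmax, 8))
  for (i in seq_len(nc)) wr(pad("", 80))
  for (i in seq_len(nc)) wr(pad(fs, 8))
  for (i in seq_len(nc)) wr(pad("", 32))

  # use the header's (possibly rounded) physical limits for scaling so the
  # reader inverts the transform exactly
  pmin_h <- as.numeric(signif(pmin_, 7)); pmax_h <- as.numeric(signif(pmax_, 7))
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(nc)) {
      dig <- round((y[i, cols] - pmin_h[i]) / (pmax_h[i] - pmin_h[i]) *
                     (dmax - dmin) + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8)); dur <- as.numeric(rd(8)); nc <- as.integer(rd(4))
  labels <- vapply(seq_len(nc), function(i) rd(16), character(1))
  for (i in seq_len(nc)) rd(80)
  for (i in seq_len(nc)) rd(8)
  pmin_ <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(nc)) rd(80)
  spr <- vapply(seq_len(nc), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(nc)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("EDF reader supports a single common sampling rate", call. = FALSE)
  fs <- spr[1L] / dur
  y <- matrix(0, nc, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nc)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[i])
        stop("malformed EDF: truncated data record ", r, call. = FALSE)
      cols <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      y[i, cols] <- (dig - dmin[i]) / (dmax[i] - dmin[i]) *
        (pmax_[i] - pmin_[i]) + pmin_[i]
    }
  }
  structure(list(y_t = y, fs = fs, sigma2_n = NA_real_,
                 subject_id = NA_integer_, trial_id = NA_integer_,
                 labels = labels),
            class = "sensor_recording")
}

#' Save / load a synthetic dataset as a plain-text container
#'
#' Directory layout: `meta.json` (spec echo, labels, ids, noise variances),
#' `leadfield.tsv`, and one `epochs/epoch_<k>.tsv` per epoch.  Everything is
#' plain text, so containers diff cleanly and survive any transport.
#'
#' @param ds Result of [generate_dataset()] (ground truth is not persisted).
#' @param dir Target directory (created if needed).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "epochs"), recursive = TRUE, showWarnings = FALSE)
  write.table(ds$lead_field$H, file.path(dir, "leadfield.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  es <- ds$epochs
  meta <- list(fs = es$epochs[[1L]]$fs,
               model_tag = ds$lead_field$model_tag,
               labels = as.character(es$labels),
               subject_ids = es$subject_ids,
               trial_ids = es$trial_ids,
               sigma2_n = vapply(es$epochs, function(e) e$sigma2_n, numeric(1)))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  for (k in seq_along(es$epochs))
    write.table(es$epochs[[k]]$y_t,
                file.path(dir, "epochs", sprintf("epoch_%04d.tsv", k)),
                sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  H <- as.matrix(read.table(file.path(dir, "leadfield.tsv"), sep = "\t"))
  dimnames(H) <- NULL
  lf <- structure(list(H = H, sensor_positions = NULL, source_positions = NULL,
                       model_tag = meta$model_tag),
                  class = "lead_field")
  files <- sort(list.files(file.path(dir, "epochs"), full.names = TRUE))
  epochs <- lapply(seq_along(files), function(k) {
    y <- as.matrix(read.table(files[k], sep = "\t")); dimnames(y) <- NULL
    structure(list(y_t = y, fs = meta$fs, sigma2_n = meta$sigma2_n[k],
                   subject_id = meta$subject_ids[k],
                   trial_id = meta$trial_ids[k]),
              class = "sensor_recording")
  })
  es <- structure(list(epochs = epochs,
                       labels = factor(meta$labels, c("negative", "positive")),
                       subject_ids = meta$subject_ids,
                       trial_ids = meta$trial_ids),
                  class = "epoch_set")
  list(lead_field = lf, epochs = es)
}

#' Dump a Gibbs chain as delimited text
#'
#' Writes `x.tsv` (kept samples x sources) and `hyper.tsv` (per-iteration
#' `sigma2`, `omega`, `lam`) into `dir` for external diagnostics.
#'
#' @param chain A `gibbs_chain`.
#' @param dir Target directory (created if needed).
#' @export
write_chain <- function(chain, dir) {
  stopifnot(inherits(chain, "gibbs_chain"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(chain$x, file.path(dir, "x.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(sigma2 = chain$sigma2, omega = chain$omega,
                         lam = chain$lam),
              file.path(dir, "hyper.tsv"), sep = "\t", row.names = FALSE)
  invisible(dir)
}
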