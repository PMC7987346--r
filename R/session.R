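# Session container, validation, and on-disk bundle IO.
#
# A session bundles everything recorded in one head-fixed linear-track imaging
# run: the binarized event-onset raster and continuous dF/F traces of all
# granule cells, the treadmill behavior (running speed, belt position), and the
# optional bulk MPP fluorescence and pupil-diameter channels. The on-disk form
# is a directory of delimited text tables plus a plain-text manifest, chosen
# for diffability and language neutrality.

#' Construct a session recording
#'
#' Assembles the per-session data bundle used by all analysis stages. All
#' per-frame channels must share the same number of frames. Frames are 1-based
#' throughout the package.
#'
#' @param raster binary matrix (n_cells x n_frames); 1 marks a calcium event
#'   onset in that frame.
#' @param dff numeric matrix (n_cells x n_frames) of dF/F traces
#'   (dimensionless).
#' @param speed numeric vector of running speed per frame (cm/s, >= 0).
#' @param position numeric vector of belt position per frame (cm, in
#'   `[0, belt_length)`).
#' @param frame_rate imaging frame rate in Hz.
#' @param belt_length belt length in cm.
#' @param mpp optional numeric vector: bulk medial perforant path fluorescence
#'   per frame (arbitrary units). `NULL` when not recorded.
#' @param pupil optional numeric vector: pupil diameter per frame (normalized,
#'   unitless). `NULL` when not recorded.
#' @param blink optional binary vector marking frames lost to blinks/saccades;
#'   required to accompany `pupil` (defaults to all-zero when `pupil` given).
#' @param session_id character label.
#' @return an object of class `dg_session`.
#' @seealso [validate_session()], [read_session()], [write_session()]
#' @export
new_session <- function(raster, dff, speed, position, frame_rate, belt_length,
                        mpp = NULL, pupil = NULL, blink = NULL,
                        session_id = "session") {
  raster <- as.matrix(raster)
  dff <- as.matrix(dff)
  if (!is.null(pupil) && is.null(blink)) blink <- numeric(ncol(raster))
  s <- structure(list(
    raster = raster, dff = dff,
    speed = as.numeric(speed), position = as.numeric(position),
    mpp = if (is.null(mpp)) NULL else as.numeric(mpp),
    pupil = if (is.null(pupil)) NULL else as.numeric(pupil),
    blink = if (is.null(blink)) NULL else as.numeric(blink),
    frame_rate = as.numeric(frame_rate),
    belt_length = as.numeric(belt_length),
    session_id = as.character(session_id)
  ), class = "dg_session")
  s
}

#' @export
print.dg_session <- function(x, ...) {
  cat(sprintf("<dg_session '%s'>: %d cells x %d frames @ %g Hz, belt %g cm\n",
              x$session_id, nrow(x$raster), ncol(x$raster),
              x$frame_rate, x$belt_length))
  cat(sprintf("  channels: raster, dff, speed, position%s%s\n",
              if (is.null(x$mpp)) "" else ", mpp",
              if (is.null(x$pupil)) "" else ", pupil"))
  invisible(x)
}

#' Number of frames / cells in a session
#' @param s a `dg_session`.
#' @return integer.
#' @export
n_frames <- function(s) ncol(s$raster)

#' @rdname n_frames
#' @export
n_cells <- function(s) nrow(s$raster)

#' Validate a session recording
#'
#' Checks every container invariant and reports violations; never throws.
#' Checked: shared frame count across channels, raster values in \{0,1\},
#' finite dF/F, speed >= 0, position in `[0, belt_length)`, positive frame
#' rate and belt length, blink mask paired with pupil.
#'
#' @param s a `dg_session`.
#' @return character vector of human-readable violations; empty iff valid.
#' @export
validate_session <- function(s) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (!is.matrix(s$raster)) add("raster: not a matrix")
  if (!is.matrix(s$dff)) add("dff: not a matrix")
  nf <- ncol(s$raster)
  if (!identical(dim(s$raster), dim(s$dff)))
    add(sprintf("dff: dimensions %s do not match raster %s",
                paste(dim(s$dff), collapse = "x"),
                paste(dim(s$raster), collapse = "x")))
  for (ch in c("speed", "position", "mpp", "pupil", "blink")) {
    x <- s[[ch]]
    if (!is.null(x) && length(x) != nf)
      add(sprintf("%s: length %d, expected n_frames = %d", ch, length(x), nf))
  }
  if (!all(s$raster %in% c(0, 1))) {
    bad <- which(!(s$raster %in% c(0, 1)))[1L]
    add(sprintf("raster: value %s at entry %d not in {0,1}",
                format(s$raster[bad]), bad))
  }
  if (anyNA(s$dff) || any(!is.finite(s$dff))) {
    bad <- which(!is.finite(s$dff), arr.ind = TRUE)[1L, ]
    add(sprintf("dff: non-finite value at cell %d, frame %d", bad[1L], bad[2L]))
  }
  if (length(s$speed) == nf && any(s$speed < 0, na.rm = TRUE))
    add(sprintf("speed: negative value at frame %d", which(s$speed < 0)[1L]))
  if (!is.numeric(s$frame_rate) || length(s$frame_rate) != 1L || s$frame_rate <= 0)
    add("frame_rate: must be a single positive number")
  if (!is.numeric(s$belt_length) || length(s$belt_length) != 1L || s$belt_length <= 0)
    add("belt_length: must be a single positive number")
  if (length(s$position) == nf && is.numeric(s$belt_length) && s$belt_length > 0) {
    out <- which(s$position < 0 | s$position >= s$belt_length)
    if (length(out))
      add(sprintf("position: value %g at frame %d outside [0, belt_length)",
                  s$position[out[1L]], out[1L]))
  }
  if (!is.null(s$pupil) && is.null(s$blink))
    add("blink: missing blink mask for pupil channel")
  if (!is.null(s$blink) && !all(s$blink %in% c(0, 1)))
    add("blink: values not in {0,1}")
  v
}

#' Write a session bundle to disk
#'
#' Writes a directory with `manifest.txt` (key: value metadata and channel
#' list), `raster.tsv`, `dff.tsv`, `behavior.tsv` (frame, speed, position) and,
#' when present, `mpp.tsv` and `pupil.tsv` (frame, diameter, blink). Absent
#' optional channels are simply omitted from the bundle and manifest.
#'
#' @param s a valid `dg_session`.
#' @param path directory to create (must not be an existing file).
#' @return `path`, invisibly.
#' @export
write_session <- function(s, path) {
  v <- validate_session(s)
  if (length(v)) stop("invalid session: ", v[1L])
  if (file.exists(path) && !dir.exists(path))
    stop("path exists and is not a directory: ", path)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  channels <- c("raster", "dff", "behavior",
                if (!is.null(s$mpp)) "mpp",
                if (!is.null(s$pupil)) "pupil")
  manifest <- c(
    paste0("session_id: ", s$session_id),
    paste0("frame_rate: ", format(s$frame_rate, digits = 17)),
    paste0("belt_length: ", format(s$belt_length, digits = 17)),
    paste0("n_cells: ", nrow(s$raster)),
    paste0("n_frames: ", ncol(s$raster)),
    paste0("channels: ", paste(channels, collapse = ","))
  )
  writeLines(manifest, file.path(path, "manifest.txt"))
  fw <- function(x, f) data.table::fwrite(data.table::as.data.table(x),
                                          file.path(path, f), sep = "\t")
  fw(s$raster, "raster.tsv")
  fw(s$dff, "dff.tsv")
  fw(data.frame(frame = seq_len(ncol(s$raster)),
                speed = s$speed, position = s$position), "behavior.tsv")
  if (!is.null(s$mpp))
    fw(data.frame(frame = seq_along(s$mpp), mpp = s$mpp), "mpp.tsv")
  if (!is.null(s$pupil))
    fw(data.frame(frame = seq_along(s$pupil), diameter = s$pupil,
                  blink = s$blink), "pupil.tsv")
  invisible(path)
}

#' Read a session bundle from disk
#'
#' Inverse of [write_session()]. Validates declared shapes against the loaded
#' tables and all container invariants; structured errors name the offending
#' channel.
#'
#' @param path bundle directory written by [write_session()].
#' @return a `dg_session`.
#' @export
read_session <- function(path) {
  mf <- file.path(path, "manifest.txt")
  if (!file.exists(mf)) stop("no manifest.txt in ", path)
  kv <- strsplit(readLines(mf), ": ", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  nc <- as.integer(meta[["n_cells"]]); nf <- as.integer(meta[["n_frames"]])
  channels <- strsplit(meta[["channels"]], ",", fixed = TRUE)[[1L]]
  fr <- function(f) as.matrix(data.table::fread(file.path(path, f), sep = "\t"))
  raster <- fr("raster.tsv")
  dff <- fr("dff.tsv")
  dimnames(raster) <- dimnames(dff) <- NULL
  if (!identical(dim(raster), c(nc, nf)))
    stop("raster: shape ", paste(dim(raster), collapse = "x"),
         " does not match manifest ", nc, "x", nf)
  beh <- data.table::fread(file.path(path, "behavior.tsv"), sep = "\t")
  if (nrow(beh) != nf)
    stop("speed/position: behavior.tsv has ", nrow(beh),
         " rows, expected n_frames = ", nf)
  mpp <- pupil <- blink <- NULL
  if ("mpp" %in% channels) {
    tab <- data.table::fread(file.path(path, "mpp.tsv"), sep = "\t")
    if (nrow(tab) != nf) stop("mpp: ", nrow(tab), " rows, expected ", nf)
    mpp <- tab$mpp
  }
  if ("pupil" %in% channels) {
    tab <- data.table::fread(file.path(path, "pupil.tsv"), sep = "\t")
    if (nrow(tab) != nf) stop("pupil: ", nrow(tab), " rows, expected ", nf)
    pupil <- tab$diameter; blink <- tab$blink
  }
  s <- new_session(raster, dff, beh$speed, beh$position,
                   frame_rate = as.numeric(meta[["frame_rate"]]),
                   belt_length = as.numeric(meta[["belt_length"]]),
                   mpp = mpp, pupil = pupil, blink = blink,
                   session_id = meta[["session_id"]])
  v <- validate_session(s)
  if (length(v)) stop("invalid bundle: ", paste(v, collapse = "; "))
  s
}
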