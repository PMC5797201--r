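#' List-mode coincidence data
#'
#' Container for timestamped prompt/delayed coincidence events plus
#' bucket-singles records. Events carry the two crystal addresses as
#' (transaxial position, ring), all 0-based.
#'
#' @param events List or data frame with integer vectors `time_ms`, `txa`,
#'   `ringa`, `txb`, `ringb` and logical `delayed`, sorted by time.
#' @param singles Data frame with `time_ms`, `bucket`, `rate` (counts/s);
#'   bucket singles are reported every couple of seconds per bucket.
#' @param duration_ms Acquisition duration (ms).
#' @param geom A `pet_geometry` (validates indices, stamps the hash).
#' @return A `pet_listmode`.
#' @export
new_listmode <- function(events, singles, duration_ms, geom) {
  ev <- list(time_ms = as.integer(events$time_ms),
             txa = as.integer(events$txa), ringa = as.integer(events$ringa),
             txb = as.integer(events$txb), ringb = as.integer(events$ringb),
             delayed = as.logical(events$delayed))
  n <- length(ev$time_ms)
  if (any(vapply(ev, length, 1L) != n)) stop2("event fields have unequal length")
  if (n > 0) {
    if (is.unsorted(ev$time_ms)) stop2("event times must be non-decreasing")
    if (any(ev$ringa >= geom$n_rings | ev$ringb >= geom$n_rings |
            ev$ringa < 0L | ev$ringb < 0L))
      stop2("event ring index out of range 0..%d", geom$n_rings - 1L)
    if (any(ev$txa >= geom$n_crystal_positions | ev$txb >= geom$n_crystal_positions |
            ev$txa < 0L | ev$txb < 0L))
      stop2("event crystal position out of range")
  }
  sg <- data.frame(time_ms = as.integer(singles$time_ms %||% integer(0)),
                   bucket = as.integer(singles$bucket %||% integer(0)),
                   rate = as.numeric(singles$rate %||% numeric(0)))
  if (nrow(sg) && any(sg$bucket < 0L | sg$bucket >= n_buckets(geom)))
    stop2("bucket id out of range 0..%d", n_buckets(geom) - 1L)
  structure(list(events = ev, singles = sg,
                 duration_ms = as.integer(duration_ms),
                 geom_hash = geometry_hash(geom)),
            class = "pet_listmode")
}

n_events <- function(lm) length(lm$events$time_ms)

#' @export
print.pet_listmode <- function(x, ...) {
  cat(sprintf("pet_listmode: %d events (%d delayed), %d singles records, %.1f s\n",
              n_events(x), sum(x$events$delayed), nrow(x$singles),
              x$duration_ms / 1000))
  invisible(x)
}

LM_MAGIC <- "PQLM"
LM_VERSION <- 1L

#' Write / read the list-mode container
#'
#' Columnar little-endian binary layout: magic "PQLM", version, event count,
#' then the event columns (`time_ms` int32, crystal addresses int16, delayed
#' flag int8), then the singles records (int32 time, int16 bucket, float64
#' rate). A JSON sidecar (`<path>.json`) carries duration, geometry hash and
#' record counts; reads validate both.
#'
#' @param lm A `pet_listmode`.
#' @param path Payload path.
#' @param geom A `pet_geometry`.
#' @export
write_listmode <- function(lm, path, geom) {
  if (!identical(lm$geom_hash, geometry_hash(geom)))
    stop2("list-mode geometry hash mismatch")
  side <- list(format = "petquant-listmode", version = LM_VERSION,
               geometry_hash = lm$geom_hash, duration_ms = lm$duration_ms,
               n_events = n_events(lm), n_singles = nrow(lm$singles))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(LM_MAGIC), con)
  writeBin(c(LM_VERSION, n_events(lm), nrow(lm$singles)), con, size = 4L,
           endian = "little")
  ev <- lm$events
  writeBin(ev$time_ms, con, size = 4L, endian = "little")
  for (f in c("txa", "ringa", "txb", "ringb"))
    writeBin(ev[[f]], con, size = 2L, endian = "little")
  writeBin(as.integer(ev$delayed), con, size = 1L)
  writeBin(lm$singles$time_ms, con, size = 4L, endian = "little")
  writeBin(lm$singles$bucket, con, size = 2L, endian = "little")
  writeBin(lm$singles$rate, con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_listmode
#' @export
read_listmode <- function(path, geom) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(side$format, "petquant-listmode")) stop2("not a list-mode container")
  if (!identical(side$geometry_hash, geometry_hash(geom)))
    stop2("list-mode geometry hash mismatch")
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, LM_MAGIC)) stop2("bad list-mode magic '%s'", magic)
  hdr <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  if (hdr[1] != LM_VERSION) stop2("unsupported list-mode version %d", hdr[1])
  ne <- hdr[2]; ns <- hdr[3]
  if (ne != side$n_events || ns != side$n_singles)
    stop2("list-mode sidecar/payload record count mismatch")
  rd <- function(n, size, signed = TRUE) {
    v <- readBin(con, "integer", n, size = size, signed = signed, endian = "little")
    if (length(v) < n) stop2("truncated list-mode record section")
    v
  }
  ev <- list(time_ms = rd(ne, 4L))
  for (f in c("txa", "ringa", "txb", "ringb")) ev[[f]] <- rd(ne, 2L)
  ev$delayed <- rd(ne, 1L) != 0L
  st <- rd(ns, 4L)
  sb <- rd(ns, 2L)
  sr <- readBin(con, "double", ns, size = 8L, endian = "little")
  if (length(sr) < ns) stop2("truncated singles section")
  new_listmode(ev, data.frame(time_ms = st, bucket = sb, rate = sr),
               side$duration_ms, geom)
}

# Map events to span-1 bins. Returns list(bin_tx, plane, valid).
event_bins <- function(lm, geom, bm = build_sino_bin_map(geom),
                       mi = michelogram_map(geom)) {
  ev <- lm$events
  N <- geom$n_crystal_positions
  bin_tx <- bm$pair2bin[cbind(ev$txa + 1L, ev$txb + 1L)]
  al <- bm$aligned[cbind(ev$txa + 1L, ev$txb + 1L)]
  r0 <- ifelse(al, ev$ringa, ev$ringb)
  r1 <- ifelse(al, ev$ringb, ev$ringa)
  plane <- mi$plane_of[cbind(r0 + 1L, r1 + 1L)]
  live <- bm$live[ev$txa + 1L] & bm$live[ev$txb + 1L]
  valid <- !is.na(bin_tx) & !is.na(plane) & live
  list(bin_tx = bin_tx, plane = plane, valid = valid, r0 = r0, r1 = r1)
}

#' Histogram a list-mode stream
#'
#' Bins prompt and delayed events into sinograms for one or more time
#' frames, and derives the head curve (counts/s), the per-second axial
#' centre-of-mass trace (motion proxy, from the single-slice-rebinned axial
#' profile of prompts), the time x bucket singles matrix and the delayed fan
#' sums per crystal. Events on dead positions or outside the radial/ring
#' acceptance are counted into a discard tally.
#'
#' @param lm A `pet_listmode`.
#' @param geom A `pet_geometry`.
#' @param frames List of `c(t0, t1)` in ms (half-open, non-overlapping);
#'   default one frame covering the acquisition.
#' @param span Output span (default the geometry's span).
#' @return List of per-frame results, each with `prompts`, `delayeds`
#'   (`pet_sinogram`), `head_curve`, `com_trace`, `bucket_singles`,
#'   `delayed_fansums` (matrix positions x rings), `n_prompts`,
#'   `n_delayeds`, `discarded`.
#' @export
histogram_listmode <- function(lm, geom, frames = NULL, span = geom$span) {
  if (is.null(frames)) frames <- list(c(0, lm$duration_ms))
  fr <- do.call(rbind, lapply(frames, as.numeric))
  if (any(fr[, 2] <= fr[, 1])) stop2("frames must have t1 > t0")
  if (any(fr[, 1] < 0) || any(fr[, 2] > lm$duration_ms))
    stop2("frames outside acquisition duration")
  o <- order(fr[, 1])
  if (nrow(fr) > 1 && any(fr[o, 1][-1] < fr[o, 2][-nrow(fr)]))
    stop2("overlapping frames")

  bm <- build_sino_bin_map(geom)
  mi <- michelogram_map(geom)
  eb <- event_bins(lm, geom, bm, mi)
  ev <- lm$events
  nb <- geom$n_radial_bins * geom$n_angles
  zr <- ring_z(geom)

  lapply(seq_len(nrow(fr)), function(i) {
    t0 <- fr[i, 1]; t1 <- fr[i, 2]
    infr <- ev$time_ms >= t0 & ev$time_ms < t1
    out <- list(frame = c(t0, t1) / 1000)
    for (kind in c("prompts", "delayeds")) {
      del <- kind == "delayeds"
      sel <- infr & (ev$delayed == del) & eb$valid
      lin <- eb$bin_tx[sel] + nb * eb$plane[sel]
      counts <- tabulate(lin + 1L, nbins = nb * mi$n_planes)
      s1 <- new_sinogram(geom, 1L,
                         array(counts, c(geom$n_radial_bins, geom$n_angles, mi$n_planes)),
                         frame = c(t0, t1) / 1000)
      out[[kind]] <- if (identical(span, 1L) || identical(span, 1)) s1
                     else reduce_span(s1, geom, span)
    }
    out$n_prompts <- sum(infr & !ev$delayed)
    out$n_delayeds <- sum(infr & ev$delayed)
    out$discarded <- sum(infr & !eb$valid)

    sec <- floor((ev$time_ms[infr] - t0) / 1000)
    nsec <- max(1L, as.integer(ceiling((t1 - t0) / 1000)))
    isdel <- ev$delayed[infr]
    out$head_curve <- data.frame(
      second = 0:(nsec - 1L),
      prompts = tabulate(sec[!isdel] + 1L, nbins = nsec),
      delayeds = tabulate(sec[isdel] + 1L, nbins = nsec))

    # axial centre of mass of prompts per second (SSR axial position, mm)
    selp <- infr & !ev$delayed & eb$valid
    zmm <- (zr[ev$ringa[selp] + 1L] + zr[ev$ringb[selp] + 1L]) / 2
    secp <- floor((ev$time_ms[selp] - t0) / 1000)
    num <- rowsum(zmm, secp)
    cnt <- tabulate(secp + 1L, nbins = nsec)
    com <- rep(NA_real_, nsec)
    com[as.integer(rownames(num)) + 1L] <- num[, 1] /
      pmax(cnt[as.integer(rownames(num)) + 1L], 1L)
    out$com_trace <- data.frame(second = 0:(nsec - 1L), com_mm = com)

    # bucket singles: mean reported rate per second x bucket
    sg <- lm$singles[lm$singles$time_ms >= t0 & lm$singles$time_ms < t1, , drop = FALSE]
    bs <- matrix(NA_real_, nsec, n_buckets(geom))
    if (nrow(sg)) {
      ss <- floor((sg$time_ms - t0) / 1000)
      agg <- rowsum(cbind(sg$rate, 1), group = ss * n_buckets(geom) + sg$bucket)
      key <- as.integer(rownames(agg))
      bs[cbind(key %/% n_buckets(geom) + 1L, key %% n_buckets(geom) + 1L)] <-
        agg[, 1] / agg[, 2]
    }
    out$bucket_singles <- bs

    # delayed fan sums: every valid delayed event contributes to both crystals
    seld <- infr & ev$delayed & eb$valid
    cryst <- c(ev$txa[seld] + geom$n_crystal_positions * ev$ringa[seld],
               ev$txb[seld] + geom$n_crystal_positions * ev$ringb[seld])
    out$delayed_fansums <- matrix(
      tabulate(cryst + 1L, nbins = geom$n_crystal_positions * geom$n_rings),
      geom$n_crystal_positions, geom$n_rings)
    out
  })
}

#' Nonparametric list-mode bootstrap resample
#'
#' Samples n events with replacement from the n originals (prompts and
#' delayeds resampled as one stream, each event keeping its type flag), then
#' restores time order by a stable sort. Singles records are copied
#' unchanged. Identical seeds give identical replicates.
#'
#' @param lm A `pet_listmode`.
#' @param seed Integer seed.
#' @return A `pet_listmode` replicate with the same event count.
#' @export
bootstrap_resample <- function(lm, seed) {
  n <- n_events(lm)
  if (n < 1L) stop2("cannot bootstrap an empty event stream")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  idx <- sample.int(n, n, replace = TRUE)
  idx <- idx[order(lm$events$time_ms[idx], method = "radix")]
  out <- lm
  out$events <- lapply(lm$events, function(v) v[idx])
  out
}
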