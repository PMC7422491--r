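# Dataset serialization: EDF (one file per subject) or delimited text (one
# file per segment), plus a manifest tying provenance to file locations.

#' Write a segment collection to disk
#'
#' With `format = "edf"`, one EDF file per subject is written: one signal
#' per channel (labeled with the bipolar channel name, physical dimension
#' uV) and one 10-second data record per (emotion, video, segment) page,
#' ordered by (emotion, video, segment). With `format = "text"`, one
#' delimited file per segment is written with header
#' `sample_index,value_uV`. Both formats produce a `manifest.csv` listing
#' every (subject, emotion, video, segment, channel) record with its file
#' (and, for EDF, record index), plus the sampling rate.
#'
#' @param dataset a non-empty [EEGSegmentSet-class].
#' @param dir output directory (created if needed).
#' @param format `"edf"` or `"text"`.
#' @return path of the manifest file, invisibly.
#' @export
writeDataset <- function(dataset, dir, format = c("edf", "text")) {
  format <- match.arg(format)
  stopifnot(is(dataset, "EEGSegmentSet"))
  if (!ncol(dataset)) stop("empty collection: nothing to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  cd <- colData(dataset)
  sm <- assay(dataset, "samples")
  design <- S4Vectors::metadata(dataset)$design
  fs <- if (!is.null(design)) samplingRate(design) else 256
  recSec <- nrow(sm) / fs

  rows <- list()
  if (format == "text") {
    for (i in seq_len(ncol(sm))) {
      f <- sprintf("s%02d_%s_v%d_p%02d_%s.csv", cd$subject[i],
                   cd$emotion[i], cd$video[i], cd$segment[i],
                   gsub("[^A-Za-z0-9]+", "", cd$channel[i]))
      .write_segment_text(sm[, i], file.path(dir, f))
      rows[[i]] <- data.frame(
        subject = cd$subject[i], emotion = as.character(cd$emotion[i]),
        video = cd$video[i], segment = cd$segment[i],
        channel = as.character(cd$channel[i]), file = f, record = 1L)
    }
  } else {
    chans <- levels(cd$channel)
    for (subj in sort(unique(cd$subject))) {
      sel <- which(cd$subject == subj)
      ord <- sel[order(as.integer(cd$emotion[sel]), cd$video[sel],
                       cd$segment[sel], as.integer(cd$channel[sel]))]
      # one record per (emotion, video, segment); every channel present
      key <- paste(cd$emotion[ord], cd$video[ord], cd$segment[ord])
      recs <- unique(key)
      signals <- lapply(chans, function(ch) {
        m <- matrix(NA_real_, nrow = nrow(sm), ncol = length(recs))
        for (r in seq_along(recs)) {
          j <- ord[key == recs[r] & cd$channel[ord] == ch]
          if (length(j) != 1L) {
            stop("subject ", subj, " record '", recs[r],
                 "' lacks channel ", ch)
          }
          m[, r] <- sm[, j]
        }
        m
      })
      names(signals) <- chans
      f <- sprintf("subject%02d.edf", subj)
      writeEDF(signals, file.path(dir, f), recordSeconds = recSec,
               recordingId = sprintf("eegbench subject %d", subj))
      first <- ord[!duplicated(key)]
      for (r in seq_along(recs)) {
        i <- first[r]
        for (ch in chans) {
          rows[[length(rows) + 1L]] <- data.frame(
            subject = subj, emotion = as.character(cd$emotion[i]),
            video = cd$video[i], segment = cd$segment[i],
            channel = ch, file = f, record = r)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$samplingRate <- fs
  manifest$format <- format
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  logMsg("info", "wrote %d segments (%s) to %s", ncol(sm), format, dir)
  invisible(mpath)
}

#' Read a dataset back from a manifest
#'
#' Reconstructs an [EEGSegmentSet-class] from the `manifest.csv` written
#' by [writeDataset()], reading EDF records or delimited segment files as
#' listed.
#'
#' @param manifestPath path to the manifest file.
#' @return an [EEGSegmentSet-class] (design metadata reduced to what the
#'   manifest records: labels, channels, sampling rate).
#' @export
readDataset <- function(manifestPath) {
  if (!file.exists(manifestPath)) {
    stop("no such manifest: ", manifestPath)
  }
  man <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
  need <- c("subject", "emotion", "video", "segment", "channel", "file",
            "record", "samplingRate", "format")
  miss <- setdiff(need, colnames(man))
  if (length(miss)) {
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  }
  dir <- dirname(manifestPath)
  fs <- man$samplingRate[1]
  segs <- vector("list", nrow(man))
  if (man$format[1] == "text") {
    for (i in seq_len(nrow(man))) {
      segs[[i]] <- as.numeric(readDelimitedSegment(
        file.path(dir, man$file[i]), samplingRate = fs))
    }
  } else {
    for (f in unique(man$file)) {
      edf <- readEDF(file.path(dir, f))
      sel <- which(man$file == f)
      for (i in sel) {
        segs[[i]] <- edf$signals[[man$channel[i]]][, man$record[i]]
      }
    }
  }
  C <- unique(lengths(segs))
  if (length(C) != 1L) {
    stop("segments in the manifest have inconsistent lengths")
  }
  samples <- do.call(cbind, segs)
  emos <- unique(man$emotion)
  chans <- unique(man$channel)
  cd <- S4Vectors::DataFrame(
    subject = as.integer(man$subject),
    emotion = factor(man$emotion, levels = emos),
    video = as.integer(man$video),
    segment = as.integer(man$segment),
    channel = factor(man$channel, levels = chans)
  )
  ord <- order(cd$subject, as.integer(cd$emotion), cd$video, cd$segment,
               as.integer(cd$channel))
  design <- datasetDesign(
    nSubjects = max(cd$subject),
    emotions = emos,
    videosPerEmotion = max(cd$video),
    segmentsPerVideo = max(cd$segment),
    channels = chans,
    samplingRate = fs,
    segmentSeconds = C / fs
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(samples = samples[, ord, drop = FALSE]),
    colData = cd[ord, ],
    metadata = list(design = design, seed = NA_integer_)
  )
  new("EEGSegmentSet", se)
}
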