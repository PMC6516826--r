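# Columnar TSV interchange for sweep sets: one file per sweep with columns
# time_ms, voltage_mV, current_pA, plus a manifest table.

#' Write a sweep set as TSV files plus a manifest
#'
#' @param sweeps a [SweepSet-class]
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix (e.g. a neuron id)
#' @return path to the manifest file, invisibly
#' @export
writeSweeps <- function(sweeps, dir, prefix = "sweep") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(sweeps), function(i) {
    sw <- sweeps[[i]]
    tt <- sweepTime(sw); w <- stepWindow(sw)
    cur <- ifelse(tt >= w[["onset"]] & tt < w[["offset"]],
                  stepAmplitude(sw), 0)
    f <- file.path(dir, sprintf("%s_%03d.tsv", prefix, i))
    utils::write.table(
      data.frame(time_ms = tt, voltage_mV = sweepVoltage(sw),
                 current_pA = cur),
      f, sep = "\t", row.names = FALSE, quote = FALSE)
    data.frame(file = basename(f), step_pA = stepAmplitude(sw),
               onset_ms = w[["onset"]], offset_ms = w[["offset"]],
               sampling_kHz = samplingRate(sw))
  })
  manifest <- file.path(dir, paste0(prefix, "_manifest.tsv"))
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a sweep set from a manifest
#'
#' @param manifest path to a manifest written by [writeSweeps()]
#' @return a [SweepSet-class]
#' @export
readSweeps <- function(manifest) {
  man <- utils::read.table(manifest, header = TRUE, sep = "\t")
  dir <- dirname(manifest)
  sweeps <- lapply(seq_len(nrow(man)), function(i) {
    d <- utils::read.table(file.path(dir, man$file[i]), header = TRUE,
                           sep = "\t")
    SweepRecording(time = d$time_ms, voltage = d$voltage_mV,
                   stepAmplitude = man$step_pA[i],
                   stepOnset = man$onset_ms[i], stepOffset = man$offset_ms[i],
                   samplingRate = man$sampling_kHz[i])
  })
  SweepSet(sweeps)
}
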