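# Minimal EDF writer used to round-trip the reader. One data record per
# second; 16-bit little-endian samples scaled to the per-channel range.

write_edf <- function(path, data, fs, labels = paste0("ch", seq_len(nrow(data))),
                      patient = "S01") {
  ns <- nrow(data)
  stopifnot(ncol(data) %% fs == 0)
  n_records <- ncol(data) / fs
  pmax_ <- apply(abs(data), 1, max)
  pmax_[pmax_ == 0] <- 1
  dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, n) {
    s <- substr(as.character(s), 1, n)
    writeChar(formatC(s, width = -n), con, eos = NULL)
  }
  pad("0", 8); pad(patient, 80); pad("rec", 80)
  pad("01.01.20", 8); pad("00.00.00", 8)
  pad(256 * (1 + ns), 8); pad("", 44)
  pad(n_records, 8); pad(1, 8); pad(ns, 4)
  for (l in labels) pad(l, 16)
  for (i in seq_len(ns)) pad("", 80)         # transducer
  for (i in seq_len(ns)) pad("uV", 8)        # physical dimension
  for (i in seq_len(ns)) pad(-pmax_[i], 8)   # physical min
  for (i in seq_len(ns)) pad(pmax_[i], 8)    # physical max
  for (i in seq_len(ns)) pad(-dmax, 8)       # digital min
  for (i in seq_len(ns)) pad(dmax, 8)        # digital max
  for (i in seq_len(ns)) pad("", 80)         # prefiltering
  for (i in seq_len(ns)) pad(fs, 8)          # samples per record
  for (i in seq_len(ns)) pad("", 32)         # reserved
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      seg <- data[s, ((r - 1) * fs + 1):(r * fs)]
      dig <- as.integer(round(seg / pmax_[s] * dmax))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
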