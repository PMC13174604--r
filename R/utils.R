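.writeTsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

.readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  as.data.frame(data.table::fread(path, sep = "\t"))
}

.geomean <- function(x) exp(mean(log(x)))

## derive a reproducible child seed (kept within 32-bit integer range)
.childSeed <- function(seed, k) as.integer((as.numeric(seed) * 7919 + k) %% .Machine$integer.max)
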