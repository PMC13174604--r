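# fixtures are generated in code: random construct libraries, count
# matrices, and tiny hand-built TE tables

randomSeqs <- function(n, L, seed = NULL, prefix = "c") {
  if (!is.null(seed)) set.seed(seed)
  setNames(vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""), ""),
    sprintf("%s%03d", prefix, seq_len(n)))
}

## small library with a CrPV positive control and (optionally) three
## spike-ins, mirroring the assay's control layout
testLibrary <- function(nCand = 5, L = 120, seed = 42, spikes = TRUE) {
  seqs <- randomSeqs(nCand, L, seed)
  fam <- rep("candidate:test", nCand)
  extra <- randomSeqs(4, L, seed + 1, prefix = "x")
  names(extra) <- c("CrPV", "spike1", "spike2", "spike3")
  if (spikes) {
    seqs <- c(seqs, extra)
    fam <- c(fam, "positive_control", rep("spike_in", 3))
  } else {
    seqs <- c(seqs, extra["CrPV"])
    fam <- c(fam, "positive_control")
  }
  ConstructLibrary(seqs, family = fam)
}

## CapCounts straight from a long spec: list(construct = list(a_cap = c(in, ip), ...))
countsFromSpec <- function(spec, condition = "control") {
  rows <- do.call(rbind, lapply(names(spec), function(id) {
    do.call(rbind, lapply(names(spec[[id]]), function(cls)
      data.frame(construct_id = id, cap_class = cls,
                 sample_id = c("in1", "ip1"),
                 umi_count = spec[[id]][[cls]], stringsAsFactors = FALSE)))
  }))
  samples <- data.frame(sample_id = c("in1", "ip1"),
                        role = c("input", "IP"), condition = condition,
                        bio_rep = 1L, tech_rep = 1L)
  CapCounts(rows, samples)
}

## brute-force Hamming distance, the assignment oracle
hammingDist <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

singleSampleSheet <- function(condition = "control") {
  data.frame(sample_id = paste0(c("in_", "ip_"), condition),
             role = c("input", "IP"), condition = condition,
             bio_rep = 1L, tech_rep = 1L, stringsAsFactors = FALSE)
}
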