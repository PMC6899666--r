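# Independent brute-force oracles. These re-derive expected values from
# first principles (SAM text, sum formulas) and share no code with the
# package's implementation paths.

# Alignment records of a SAM text file.
read_sam_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      cigar = character(), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(qname = vapply(f, `[`, "", 1L),
             flag = as.integer(vapply(f, `[`, "", 2L)),
             rname = vapply(f, `[`, "", 3L),
             pos = as.integer(vapply(f, `[`, "", 4L)),
             cigar = vapply(f, `[`, "", 6L),
             stringsAsFactors = FALSE)
}

# Reference-space aligned blocks of one alignment: M/=/X/D cover the
# reference, N skips it, I/S/H/P consume none.
cigar_blocks <- function(pos, cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  lens <- as.integer(sub(".$", "", ops))
  typ <- substring(ops, nchar(ops))
  cur <- pos; bs <- integer(); be <- integer(); open_s <- NA_integer_
  for (i in seq_along(typ)) {
    if (typ[i] %in% c("M", "=", "X", "D")) {
      if (is.na(open_s)) open_s <- cur
      cur <- cur + lens[i]
    } else if (typ[i] == "N") {
      if (!is.na(open_s)) { bs <- c(bs, open_s); be <- c(be, cur - 1L) }
      open_s <- NA_integer_
      cur <- cur + lens[i]
    }
  }
  if (!is.na(open_s)) { bs <- c(bs, open_s); be <- c(be, cur - 1L) }
  cbind(start = bs, end = be)
}

.keep_primary <- function(flag) {
  bitwAnd(flag, 4L) == 0L & bitwAnd(flag, 256L) == 0L &
    bitwAnd(flag, 2048L) == 0L
}

# Per-base depth over [lo, hi] by walking every record's aligned blocks.
brute_pileup <- function(sam_path, chrom, lo, hi) {
  rec <- read_sam_records(sam_path)
  depth <- integer(hi - lo + 1L)
  for (i in seq_len(nrow(rec))) {
    if (!.keep_primary(rec$flag[i]) || rec$rname[i] != chrom) next
    b <- cigar_blocks(rec$pos[i], rec$cigar[i])
    for (j in seq_len(nrow(b))) {
      s <- max(b[j, 1L], lo); e <- min(b[j, 2L], hi)
      if (s <= e) depth[(s - lo + 1L):(e - lo + 1L)] <-
          depth[(s - lo + 1L):(e - lo + 1L)] + 1L
    }
  }
  depth
}

# Reads with >= 1 aligned base in [lo, hi], each counted once.
brute_count <- function(sam_path, chrom, lo, hi) {
  rec <- read_sam_records(sam_path)
  n <- 0L
  for (i in seq_len(nrow(rec))) {
    if (!.keep_primary(rec$flag[i]) || rec$rname[i] != chrom) next
    b <- cigar_blocks(rec$pos[i], rec$cigar[i])
    if (any(b[, 1L] <= hi & b[, 2L] >= lo)) n <- n + 1L
  }
  n
}

# Primary mapped records in the whole file.
brute_total_mapped <- function(sam_path) {
  rec <- read_sam_records(sam_path)
  sum(.keep_primary(rec$flag))
}

# Textbook sum-formula Pearson correlation.
pearson_textbook <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}
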