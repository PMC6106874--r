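# PLINK1 binary fileset (.bed/.bim/.fam) codec ------------------------------
#
# .bed layout: magic bytes 0x6c 0x1b, mode byte 0x01 (SNP-major), then
# ceiling(n_samples/4) bytes per SNP. Two bits per genotype, least
# significant pair first: 00 homozygous A1 (count 2), 01 missing,
# 10 heterozygous (count 1), 11 homozygous A2 (count 0).

# 256 x 4 lookup: byte value -> four A1 counts (NA = missing)
bed_decode_table <- local({
  code_to_count <- c(2L, NA_integer_, 1L, 0L)   # 00, 01, 10, 11
  tab <- matrix(NA_integer_, 256, 4)
  for (b in 0:255) {
    v <- b
    for (k in 1:4) {
      tab[b + 1, k] <- code_to_count[(v %% 4L) + 1L]
      v <- v %/% 4L
    }
  }
  tab
})

count_to_code <- function(x) {
  # A1 count {0,1,2,NA} -> 2-bit code {3,2,0,1}
  code <- integer(length(x))
  code[is.na(x)] <- 1L
  code[!is.na(x) & x == 0L] <- 3L
  code[!is.na(x) & x == 1L] <- 2L
  code[!is.na(x) & x == 2L] <- 0L
  code
}

#' Read a PLINK1 binary genotype fileset
#'
#' Decodes a SNP-major `.bed` file with its `.bim`/`.fam` companions into a
#' [geno_matrix()] of A1-allele counts. Round-trips bit-exactly through
#' [write_plink1()].
#'
#' @param prefix Path prefix; `<prefix>.bed`, `.bim`, `.fam` must exist.
#' @return A [geno_matrix()].
#' @export
read_plink1 <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop_dyad(paste("missing file:", f), "io")
  }
  marker_raw <- read.table(bim, col.names = c("chr", "snp", "cm", "pos",
                                              "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam_raw <- read.table(fam, col.names = c("fid", "iid", "pat", "mat",
                                           "sex", "pheno"))
  n <- nrow(fam_raw)
  m <- nrow(marker_raw)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop_dyad(".bed magic bytes not found", "format")
  }
  if (raw[3] != as.raw(0x01)) {
    stop_dyad(".bed is not SNP-major (mode byte != 0x01)", "format")
  }
  bps <- ceiling(n / 4)                 # bytes per SNP
  if (length(raw) - 3L != bps * m) {
    stop_dyad(sprintf(".bed payload is %d bytes, expected %d for %d samples x %d SNPs",
                      length(raw) - 3L, bps * m, n, m), "length")
  }
  payload <- as.integer(raw[-(1:3)])
  # decode: per byte -> 4 counts, then trim padding rows per SNP
  counts <- bed_decode_table[payload + 1L, , drop = FALSE]  # (bps*m) x 4
  full <- matrix(t(counts), nrow = 4L * bps)                # (4*bps) x m
  values <- full[seq_len(n), , drop = FALSE]                # samples x SNPs
  marker <- tibble(snp = marker_raw$snp, chr = marker_raw$chr,
                   pos = marker_raw$pos, a1 = marker_raw$a1,
                   a2 = marker_raw$a2)
  samples <- tibble(sample_id = as.character(fam_raw$iid),
                    sex = as.integer(fam_raw$sex),
                    pheno = fam_raw$pheno)
  geno_matrix(values, marker, samples)
}

#' Write a PLINK1 binary genotype fileset
#'
#' @param geno A [geno_matrix()].
#' @param prefix Output path prefix.
#' @return Invisibly, `prefix`.
#' @export
write_plink1 <- function(geno, prefix) {
  stopifnot(inherits(geno, "geno_matrix"))
  x <- geno$values
  if (geno$haploid) x <- 2L * x       # hemizygous stored as homozygous codes
  n <- nrow(x)
  m <- ncol(x)
  bps <- ceiling(n / 4)
  padded <- matrix(3L, nrow = 4L * bps, ncol = m)  # pad = hom A2 (count 0)
  padded[seq_len(n), ] <- count_to_code(x)
  # pack 4 codes per byte, LSB pair first
  i1 <- seq(1, 4L * bps, by = 4)
  bytes <- padded[i1, , drop = FALSE] +
    4L * padded[i1 + 1L, , drop = FALSE] +
    16L * padded[i1 + 2L, , drop = FALSE] +
    64L * padded[i1 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  write.table(
    data.frame(geno$marker$chr, geno$marker$snp, 0, geno$marker$pos,
               geno$marker$a1, geno$marker$a2),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  write.table(
    data.frame(geno$samples$sample_id, geno$samples$sample_id, 0, 0,
               geno$samples$sex, geno$samples$pheno),
    paste0(prefix, ".fam"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(prefix)
}
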