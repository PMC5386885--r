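#' Build a multi-chromosome SNP map
#'
#' Draws SNP physical positions uniformly along each chromosome, sorts and
#' de-duplicates them, and derives genetic positions from a constant
#' recombination rate. The map plays the role of an array's mapped, ordered
#' SNP positions on a reference assembly.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param snps_per_chrom Integer SNP count per chromosome; either a single
#'   value recycled to all chromosomes or a vector of length `n_chrom`.
#'   Each must be >= 2.
#' @param chrom_length_bp Chromosome length in base pairs (recycled likewise).
#' @param cm_per_mb Constant genetic map rate, centimorgans per megabase
#'   (> 0). Default 1 cM/Mb.
#' @param seed Integer seed controlling position sampling.
#'
#' @return A tibble of class `genome_map` with columns `chrom`, `snp_id`,
#'   `pos_bp` (1-based, strictly increasing within chromosome) and `pos_cm`
#'   (`pos_bp * cm_per_mb / 1e6`).
#' @examples
#' gmap <- build_genome_map(n_chrom = 2, snps_per_chrom = 100,
#'                          chrom_length_bp = 5e7, seed = 1)
#' @export
build_genome_map <- function(n_chrom, snps_per_chrom, chrom_length_bp = 1e8,
                             cm_per_mb = 1.0, seed = 1L) {
  assert_that(n_chrom >= 1, "`n_chrom` must be >= 1")
  snps_per_chrom <- rep_len(as.integer(snps_per_chrom), n_chrom)
  chrom_length_bp <- rep_len(chrom_length_bp, n_chrom)
  assert_that(all(snps_per_chrom >= 2), "`snps_per_chrom` must be >= 2")
  assert_that(is.numeric(cm_per_mb) && cm_per_mb > 0, "`cm_per_mb` must be > 0")
  assert_that(all(chrom_length_bp >= snps_per_chrom),
              "`chrom_length_bp` too short for the requested SNP count")

  rows <- with_seed(derive_seed(seed, "genome_map"), {
    purrr::map(seq_len(n_chrom), function(c_idx) {
      n <- snps_per_chrom[c_idx]
      len <- chrom_length_bp[c_idx]
      pos <- sort(unique(sample.int(len, n)))
      tries <- 0L
      while (length(pos) < n) {
        tries <- tries + 1L
        if (tries > 100L) {
          stop("could not draw ", n, " distinct positions on chromosome chr",
               c_idx, call. = FALSE)
        }
        pos <- sort(unique(c(pos, sample.int(len, n - length(pos)))))
      }
      tibble::tibble(
        chrom = paste0("chr", c_idx),
        snp_id = sprintf("chr%d_snp%05d", c_idx, seq_len(n)),
        pos_bp = pos,
        pos_cm = pos * cm_per_mb / 1e6
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "cm_per_mb") <- cm_per_mb
  class(out) <- c("genome_map", class(out))
  out
}

# Split a genome_map into per-chromosome row indices (map order preserved).
chrom_index <- function(map) split(seq_len(nrow(map)), map$chrom)[unique(map$chrom)]
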