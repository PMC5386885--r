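#' Write a population's genotypes to VCF v4.2
#'
#' Phased haplotypes are written as `0|1`-style GT fields (haplotype 1
#' first; for offspring that is the paternally inherited gamete). With
#' `genotypes` supplied instead, unphased `0/1` calls are written and
#' missing cells become `./.`, which is the layout used for masked panels.
#'
#' @param pop A `phased_pop` (used for map and phased haplotypes).
#' @param path Output file path.
#' @param genotypes Optional unphased individual x SNP matrix (with `NA`)
#'   to write instead of the phased truth.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(pop, path, genotypes = NULL) {
  map <- pop$map
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=salimpute",
    paste0("##contig=<ID=", unique(map$chrom), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (is.null(genotypes)) {
    ids <- rownames(pop$h1)
    gt <- matrix(paste0(t(pop$h1), "|", t(pop$h2)), nrow(map), length(ids),
                 dimnames = list(NULL, ids))
  } else {
    ids <- rownames(genotypes)
    code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- t(matrix(ifelse(is.na(genotypes), "./.",
                          code[as.character(genotypes)]),
                   nrow(genotypes), ncol(genotypes)))
    colnames(gt) <- ids
  }
  body <- cbind(map$chrom, map$pos_bp, map$snp_id, "A", "C", ".", "PASS",
                ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"), con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write the pedigree as CSV
#' @param pedigree Pedigree tibble.
#' @param path Output path.
#' @export
write_pedigree_csv <- function(pedigree, path) {
  readr::write_csv(
    dplyr::select(pedigree, "id", "sire", "dam", "sex", "family_id",
                  "generation"), path)
  invisible(path)
}

#' Write the trait table as CSV
#' @param traits A `trait_table`.
#' @param path Output path.
#' @export
write_phenotypes_csv <- function(traits, path) {
  readr::write_csv(
    dplyr::select(traits, "id", "sex", "lice_count", "lice_transformed",
                  "weight", "true_bv_lice", "true_bv_weight"), path)
  invisible(path)
}

#' Write the SNP map in PLINK .map layout
#'
#' Four whitespace-separated columns: chromosome, SNP id, genetic position
#' (cM), physical position (bp).
#'
#' @param map A `genome_map`.
#' @param path Output path.
#' @export
write_plink_map <- function(map, path) {
  utils::write.table(
    data.frame(chrom = map$chrom, snp_id = map$snp_id,
               cm = map$pos_cm, bp = map$pos_bp),
    path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(path)
}

#' Export a simulated population and traits to a directory
#'
#' Writes `population.vcf` (phased truth), `pedigree.csv`,
#' `phenotypes.csv` and `snps.map`.
#'
#' @param pop A `phased_pop`.
#' @param traits Optional `trait_table`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_population <- function(pop, traits = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    write_vcf(pop, file.path(dir, "population.vcf")),
    write_pedigree_csv(pop$pedigree, file.path(dir, "pedigree.csv")),
    write_plink_map(pop$map, file.path(dir, "snps.map"))
  )
  if (!is.null(traits)) {
    paths <- c(paths,
               write_phenotypes_csv(traits, file.path(dir, "phenotypes.csv")))
  }
  invisible(paths)
}

#' Read a genotype matrix from a VCF file
#'
#' Thin wrapper over `vcfR` returning the individual x SNP 0/1/2 dosage
#' matrix (`NA` for missing) plus the SNP map columns.
#'
#' @param path VCF path.
#' @return List with `genotypes` and `map` (tibble: `chrom`, `snp_id`,
#'   `pos_bp`).
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count1 <- function(x) {
    ifelse(is.na(x) | x %in% c("./.", ".|."), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", x), "/"),
                  function(a) sum(a == "1"), integer(1)))
  }
  G <- apply(gt, 2L, count1)
  rownames(G) <- rownames(gt)
  list(genotypes = t(G),
       map = tibble::tibble(chrom = vcfR::getCHROM(v),
                            snp_id = vcfR::getID(v),
                            pos_bp = vcfR::getPOS(v)))
}

#' Read a SNP-details table (supplementary-file layout)
#'
#' Reads a delimited table describing a SNP panel. Column mapping: the SNP
#' identifier column may be named `snp_id`, `SNP`, `snp`, `marker` or
#' `Name`; chromosome `chrom`/`chr`/`Chromosome`; position
#' `pos_bp`/`pos`/`Position`. Extra columns are kept.
#'
#' @param path CSV/TSV path.
#' @return Tibble with at least `snp_id`, and `chrom`/`pos_bp` when present.
#' @export
read_snp_details <- function(path) {
  df <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  pick <- function(cands) {
    hit <- intersect(cands, names(df))
    if (length(hit) > 0) hit[1] else NULL
  }
  id_col <- pick(c("snp_id", "SNP", "snp", "marker", "Name"))
  assert_that(!is.null(id_col), "no SNP id column found")
  out <- dplyr::rename(df, snp_id = dplyr::all_of(id_col))
  chr_col <- pick(c("chrom", "chr", "Chromosome"))
  if (!is.null(chr_col) && chr_col != "chrom") {
    out <- dplyr::rename(out, chrom = dplyr::all_of(chr_col))
  }
  pos_col <- pick(c("pos_bp", "pos", "Position"))
  if (!is.null(pos_col) && pos_col != "pos_bp") {
    out <- dplyr::rename(out, pos_bp = dplyr::all_of(pos_col))
  }
  out
}

#' Read a family/phenotype table (supplementary-file layout)
#'
#' Expects an id column (`id`/`ID`/`animal`), optional `sire`, `dam`,
#' `sex`, and phenotype columns; returned as-is with normalized names.
#'
#' @param path CSV/TSV path.
#' @return Tibble.
#' @export
read_family_phenotypes <- function(path) {
  df <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  nm <- names(df)
  nm[nm %in% c("ID", "animal", "Animal")] <- "id"
  nm[nm %in% c("Sire", "father")] <- "sire"
  nm[nm %in% c("Dam", "mother")] <- "dam"
  nm[nm %in% c("Sex")] <- "sex"
  names(df) <- nm
  assert_that("id" %in% nm, "no id column found")
  df
}
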