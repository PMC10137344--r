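marker_ids <- function(genome) {
  paste0("chr", genome$chromosome, "_",
         vcf_positions(genome))
}

# physical positions synthesized at 1 cM = 1 Mb (1 Morgan = 100 Mb), 1-based
vcf_positions <- function(genome) {
  as.integer(round(genome$positions * 1e8)) + 1L
}

#' Export a population to a plain-text VCF 4.2 file
#'
#' Phased diploid GT records (`hap1|hap2`), contigs `chr1..chrN`, 1-based
#' physical positions synthesized at 1 cM = 1 Mb.  Sex, generation and
#' pedigree are preserved in `##kisim_*` header lines so that
#' [import_vcf()] round-trips the population exactly.
#'
#' @param pop A `population`.
#' @param genome The genome map.
#' @param path Output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
export_vcf <- function(pop, genome, path) {
  n <- n_individuals(pop)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=kisim_", packageVersion("kisim")),
               paste0("##contig=<ID=chr", seq_len(genome$n_chromosomes),
                      ",length=",
                      as.integer(round(genome$chromosome_length * 1e8)) + 1L,
                      ">"),
               paste0("##kisim_sex=", paste(pop$sex, collapse = ",")),
               paste0("##kisim_generation=",
                      paste(pop$generation, collapse = ",")),
               paste0("##kisim_sire=", paste(pop$sire, collapse = ",")),
               paste0("##kisim_dam=", paste(pop$dam, collapse = ",")),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", pop$id),
                     collapse = "\t")), con)
  gt <- matrix(paste0(t(pop$hap1), "|", t(pop$hap2)),
               nrow = genome$n_markers)  # markers x individuals
  body <- cbind(paste0("chr", genome$chromosome), vcf_positions(genome),
                marker_ids(genome), "A", "G", ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Import a population from a VCF file
#'
#' Reads phased diploid genotypes with `vcfR`; `##kisim_*` header lines
#' (if present) restore sex, generation and pedigree, otherwise those
#' fields are `NA`.
#'
#' @param path Path to a `.vcf` (or `.vcf.gz`) file.
#' @return A `population`.
#' @export
import_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(is.na(gt))) stop("malformed VCF: missing GT records")
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  if (!all(c(a1, a2) %in% c("0", "1")))
    stop("malformed VCF: non-biallelic GT encountered")
  hap1 <- t(matrix(as.integer(a1), nrow = nrow(gt)))
  hap2 <- t(matrix(as.integer(a2), nrow = nrow(gt)))
  ids <- colnames(gt)
  meta_vec <- function(key) {
    ln <- grep(paste0("^##kisim_", key, "="), v@meta, value = TRUE)
    if (length(ln) != 1) return(rep(NA_character_, length(ids)))
    strsplit(sub(paste0("^##kisim_", key, "="), "", ln), ",")[[1]]
  }
  sx <- meta_vec("sex"); gen <- meta_vec("generation")
  sire <- meta_vec("sire"); dam <- meta_vec("dam")
  sire[sire == "NA"] <- NA; dam[dam == "NA"] <- NA
  new_population(ids, sx, gen, sire, dam, hap1, hap2)
}

#' Export a dosage matrix as tab-separated text
#'
#' Individuals x markers 0/1/2 values with a header row of marker ids and
#' individual ids in the first column.
#'
#' @param pop A `population` (or a dosage matrix with rownames).
#' @param genome Genome map (for marker ids; optional for plain matrices).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_dosage <- function(pop, genome = NULL, path) {
  Z <- if (inherits(pop, "population")) genotypes(pop) else pop
  colnames(Z) <- if (!is.null(genome)) marker_ids(genome)
                 else colnames(Z) %||% paste0("m", seq_len(ncol(Z)))
  df <- data.frame(id = rownames(Z) %||% paste0("ind", seq_len(nrow(Z))),
                   Z, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dosage matrix written by [export_dosage()]
#' @param path Input path.
#' @return Integer matrix with individual ids as rownames.
#' @export
read_dosage <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  Z <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(Z) <- "integer"
  rownames(Z) <- df[[1]]
  Z
}

#' Write an ideal-individual specification file
#'
#' Tab-separated columns `marker_id`, `chromosome`, `position`,
#' `beneficial_allele`, `weight`, `subsystem`; [read_ideal()] round-trips
#' exactly.  `marker_id` holds the marker's column index in the dosage
#' matrix when no genome is supplied.
#'
#' @param ideal An `ideal_individual`.
#' @param path Output path.
#' @param genome Optional genome map for chromosome/position annotation.
#' @return `path`, invisibly.
#' @export
write_ideal <- function(ideal, path, genome = NULL) {
  df <- data.frame(
    marker_id = ideal$locus,
    chromosome = if (!is.null(genome)) genome$chromosome[ideal$locus]
                 else NA_integer_,
    position = if (!is.null(genome)) vcf_positions(genome)[ideal$locus]
               else NA_integer_,
    beneficial_allele = ideal$allele,
    weight = ideal$weight,
    subsystem = ideal$subsystem)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ideal-individual specification file
#' @param path Path written by [write_ideal()].
#' @return An `ideal_individual`.
#' @export
read_ideal <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  req <- c("marker_id", "beneficial_allele", "weight")
  if (!all(req %in% names(df)))
    stop("ideal spec must contain columns ", paste(req, collapse = ", "))
  new_ideal(df$marker_id, df$beneficial_allele, df$weight,
            df$subsystem %||% "trait")
}

#' Write a run manifest
#'
#' Records everything needed to replay a run bitwise: the configuration,
#' master seed, named sub-stream seeds, package version, timestamp and an
#' MD5 inventory of the produced files.
#'
#' @param config A `breeding_config`.
#' @param files Character vector of output files to checksum.
#' @param path Manifest output path (YAML).
#' @param substreams Named sub-stream labels to record (defaults cover the
#'   package's streams).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, files, path,
                           substreams = c("genome", "founders", "trait",
                                          "split", "hist", "phenotype",
                                          "sel", "mei", "bayesb", "ideal")) {
  seeds <- vapply(substreams, function(s) derive_seed(config$seed, s), 0L)
  man <- list(package = "kisim",
              version = as.character(packageVersion("kisim")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              master_seed = config$seed,
              substream_seeds = as.list(seeds),
              config = unclass(config),
              files = lapply(files[file.exists(files)], function(f)
                list(path = f, md5 = unname(tools::md5sum(f)))))
  yaml::write_yaml(man, path)
  invisible(path)
}
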