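#' Write genotypes and a marker map
#'
#' Writes a tab-delimited 0/1/2 genotype matrix (rows are individuals,
#' columns SNPs, with a header of SNP ids and an `id` column) to
#' `<prefix>.geno` and a three-column map (`snp_id`, `position_cm`,
#' `position_bp`) to `<prefix>.map`.
#'
#' @param X 0/1/2 genotype matrix.
#' @param map Data.frame with `snp_id`, `position_cm`, `position_bp`.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_genotypes <- function(X, map, prefix) {
  stopifnot(ncol(X) == nrow(map))
  geno <- data.frame(id = seq_len(nrow(X)), X, check.names = FALSE)
  colnames(geno) <- c("id", map$snp_id)
  utils::write.table(geno, paste0(prefix, ".geno"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(map[, c("snp_id", "position_cm", "position_bp")],
                     paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(prefix)
}

#' Read genotypes and a marker map
#'
#' Reads the pair of files written by [write_genotypes()] and derives the
#' heterozygote indicator matrix. Entries outside \{0, 1, 2\} (including
#' missing values) and unsorted maps are rejected.
#'
#' @param prefix Path prefix of the `.geno` / `.map` pair.
#' @return List with `X` (dosage matrix), `W` (heterozygote indicator) and
#'   `map`.
#' @export
read_genotypes <- function(prefix) {
  geno <- utils::read.table(paste0(prefix, ".geno"), header = TRUE,
                            sep = "\t", check.names = FALSE)
  map <- utils::read.table(paste0(prefix, ".map"), header = TRUE,
                           sep = "\t")
  X <- as.matrix(geno[, -1, drop = FALSE])
  if (ncol(X) != nrow(map)) stop("genotype/map dimension mismatch")
  if (anyNA(X)) stop("missing genotypes are not supported")
  if (!all(X %in% 0:2)) stop("genotypes must be coded 0/1/2")
  if (is.unsorted(map$position_cm, strictly = TRUE)) {
    stop("map positions must be strictly increasing")
  }
  storage.mode(X) <- "integer"
  list(X = X, W = matrix(as.integer(X == 1L), nrow(X), ncol(X)),
       map = map)
}

#' Marker map of a panel
#' @param pop A `wf_population`.
#' @param panel A `marker_panel`.
#' @return Data.frame with `snp_id`, `position_cm`, `position_bp`.
#' @export
panel_map <- function(pop, panel) {
  idx <- panel$snp_indices
  data.frame(snp_id = paste0("snp", idx),
             position_cm = pop$positions_cm[idx],
             position_bp = pop$positions_bp[idx])
}

#' Write a phenotype file
#' @param y Phenotype vector.
#' @param path Output path (two tab-separated columns: `individual_id`,
#'   `y`).
#' @export
write_phenotype <- function(y, path) {
  utils::write.table(data.frame(individual_id = seq_along(y), y = y),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype file
#' @param path Path written by [write_phenotype()].
#' @return Numeric phenotype vector.
#' @export
read_phenotype <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  y <- tab[[ncol(tab)]]
  if (anyNA(y)) stop("missing phenotypes are not supported")
  as.numeric(y)
}

#' Export a panel as VCF 4.2
#'
#' Writes phased genotypes (`GT` of the two haplotypes) for the panel
#' SNPs. Alleles are coded REF=A (ancestral), ALT=T (derived).
#'
#' @param pop A `wf_population`.
#' @param panel A `marker_panel` (default: all sites).
#' @param path Output `.vcf` path.
#' @export
write_vcf <- function(pop, panel = NULL, path) {
  idx <- if (is.null(panel)) seq_along(pop$freqs) else panel$snp_indices
  n <- pop$n_individuals
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=1>",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT",
                     paste0("ind", seq_len(n))), collapse = "\t"), con)
  H <- pop$haplotypes
  for (j in idx) {
    g <- paste0(as.integer(H[seq(1, 2 * n, by = 2), j]), "|",
                as.integer(H[seq(2, 2 * n, by = 2), j]))
    writeLines(paste(c("1", pop$positions_bp[j], paste0("snp", j), "A",
                       "T", ".", "PASS", ".", "GT", g), collapse = "\t"),
               con)
  }
  invisible(path)
}

config_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2)
  unname(tools::md5sum(f))
}

provenance_line <- function(config, seed) {
  sprintf("# dombayes v%s\tconfig_hash=%s\tseed=%s",
          as.character(utils::packageVersion("dombayes")),
          config_hash(config), format(seed))
}

#' Parse the provenance comment of a results file
#' @param path A file written by [write_scan()] or [write_results()].
#' @return List with `config_hash` and `seed`.
#' @export
read_provenance <- function(path) {
  line <- readLines(path, n = 1)
  if (!startsWith(line, "#")) stop("no provenance line found")
  fields <- strsplit(line, "\t")[[1]]
  kv <- strsplit(grep("=", fields, value = TRUE), "=")
  out <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  out$seed <- as.integer(out$seed)
  out
}

#' Write a window scan as TSV
#'
#' Fixed column order with a leading provenance comment (package version,
#' config hash, seed) so any published scan can be regenerated from its
#' configuration and master seed.
#'
#' @param scan A `window_scan` (or compatible data.frame).
#' @param path Output path.
#' @param config Configuration object hashed into the provenance line.
#' @param seed Master seed recorded in the provenance line.
#' @export
write_scan <- function(scan, path, config = NULL, seed = NA) {
  cols <- c("anchor_snp", "start_cm", "end_cm", "n_snps", "wppa",
            "mean_sigma2_gw", "mean_vd_w", "e_sigma2_gw")
  writeLines(provenance_line(config, seed), path)
  suppressWarnings(
    utils::write.table(as.data.frame(scan)[, cols, drop = FALSE], path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       append = TRUE))
  invisible(path)
}

#' Write an experiment results table as TSV
#' @param results Data.frame from [run_experiment()].
#' @param path Output path.
#' @inheritParams write_scan
#' @export
write_results <- function(results, path, config = NULL, seed = NA) {
  writeLines(provenance_line(config, seed), path)
  suppressWarnings(
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Reads nested configuration (demography, trait, prior, MCMC, scan
#' sections) used by the command-line interface.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
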