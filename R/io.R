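#' Read a haploid VCF plus population panel
#'
#' Accepts haploid GT calls (`0` / `1`) and homozygous diploid calls
#' (`0/0`, `1|1`, ...). Heterozygous calls mark a site for removal (the
#' intended data are haploid genomes, where heterozygotes are artefacts;
#' random resolution would distort the SFS), as do multiallelic sites and
#' sites with missing calls; all removals are counted in the provenance.
#' The ancestral allele is taken from the `AA` INFO tag when present
#' (sites with `AA` equal to ALT are repolarized); otherwise REF is assumed
#' ancestral and the dataset is flagged unpolarized.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param panel Path to a two-column tab-delimited file (`sample`,
#'   `population`), or an equivalent data frame. Every VCF sample must be
#'   listed.
#' @return A [hap_dataset()].
#' @export
read_haploid_vcf <- function(path, panel) {
  if (is.character(panel)) panel <- read_panel(panel)
  panel <- as_tibble(panel)
  names(panel)[1:2] <- c("id", "pop")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  missing_panel <- setdiff(samples, panel$id)
  if (length(missing_panel))
    abort(paste0("sample(s) missing from panel: ",
                 paste(missing_panel, collapse = ", ")))
  panel <- panel[match(samples, panel$id), ]

  multi <- grepl(",", fix$ALT, fixed = TRUE) | is.na(fix$ALT) |
    nchar(fix$REF) != 1 | nchar(fix$ALT) != 1
  coded <- matrix(NA_integer_, nrow(gt), ncol(gt))
  for (k in seq_len(ncol(gt))) {
    g <- sub("|", "/", gt[, k], fixed = TRUE)
    coded[g %in% c("0", "0/0"), k] <- 0L
    coded[g %in% c("1", "1/1"), k] <- 1L
  }
  het_site <- rowSums(matrix(gt %in% c("0/1", "1/0", "0|1", "1|0"),
                             nrow = nrow(gt))) > 0
  miss_site <- rowSums(is.na(coded)) > 0 & !het_site
  keep <- !multi & !het_site & !miss_site
  n_multi <- sum(multi)
  n_het <- sum(het_site & !multi)
  n_miss <- sum(miss_site & !multi & !het_site)

  info <- vcfR::extract.info(v, element = "AA")
  polarized <- !all(is.na(info))
  geno <- coded[keep, , drop = FALSE]
  if (polarized) {
    aa <- toupper(info[keep])
    flip <- !is.na(aa) & aa == toupper(fix$ALT[keep])
    geno[flip, ] <- 1L - geno[flip, ]
  }
  sites <- tibble(contig = fix$CHROM[keep],
                  pos = as.integer(fix$POS[keep]) - 1L)  # 0-based internally
  inform(paste0("read_haploid_vcf: kept ", sum(keep), " site(s); dropped ",
                n_multi, " multiallelic, ", n_het, " heterozygous, ",
                n_miss, " with missing calls"))
  # drop sites monomorphic across all samples
  poly <- rowSums(geno) > 0 & rowSums(geno) < ncol(geno)
  hap_dataset(geno = geno[poly, , drop = FALSE],
              sites = sites[poly, , drop = FALSE],
              samples = panel, polarized = polarized,
              provenance = list(source = path,
                                dropped_multiallelic = n_multi,
                                dropped_heterozygous = n_het,
                                dropped_missing = n_miss,
                                dropped_monomorphic = sum(!poly)))
}

#' @rdname read_haploid_vcf
#' @export
read_panel <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("id", "pop"),
                          colClasses = "character")
  as_tibble(df)
}

#' Write a dataset as haploid VCF plus panel file
#'
#' One pseudo-contig per locus, haploid `GT` calls, `AA` INFO tag carrying
#' the ancestral allele for polarized data. `write_vcf()` and
#' [read_haploid_vcf()] round-trip.
#'
#' @param ds A `hap_dataset`.
#' @param path Output VCF path.
#' @param panel_path Optional output path for the two-column panel file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(ds, path, panel_path = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=splitmig",
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ds$samples$id), collapse = "\t"))
  n <- n_sites(ds)
  body <- character(n)
  if (n > 0) {
    gt <- apply(ds$geno, 1, paste, collapse = "\t")
    body <- paste(ds$sites$contig, ds$sites$pos + 1L, ".", "A", "T", ".",
                  "PASS", if (ds$polarized) "AA=A" else ".", "GT", gt,
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
  if (!is.null(panel_path))
    writeLines(paste(ds$samples$id, ds$samples$pop, sep = "\t"), panel_path)
  invisible(path)
}

#' Run configuration with provenance
#'
#' Bundles the settings of a pipeline run; defaults follow the package's
#' standard analysis settings (10 optimization starts, 150 bootstrap
#' replicates, recombination-class breaks at 1.5 / 3 / 14.5 cM/Mb,
#' `mu = 5.21e-9`, 15 generations per year).
#'
#' @param seed Master seed (required; every stochastic stage records it).
#' @param n_starts,n_mc,n_boot Inference settings.
#' @param breaks Recombination-class boundaries.
#' @param scaling A [scaling_config()].
#' @param ... Further named settings stored verbatim.
#' @return List of class `run_config` with a provenance block.
#' @export
run_config <- function(seed, n_starts = 10, n_mc = 20000, n_boot = 150,
                       breaks = c(0, 1.5, 3, 14.5),
                       scaling = scaling_config(), ...) {
  if (missing(seed)) abort("a master seed is required")
  structure(list(seed = as.integer(seed), n_starts = n_starts, n_mc = n_mc,
                 n_boot = n_boot, breaks = breaks, scaling = scaling,
                 extra = list(...),
                 provenance = list(
                   package = "splitmig",
                   version = as.character(utils::packageVersion("splitmig")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
            class = "run_config")
}

#' Write a fit report as structured text
#'
#' Serializes a fit (and optional AIC table / confidence intervals) as a
#' flat key-value text report with scaled and physical parameter values and
#' the seeds needed to reproduce the run.
#'
#' @param fit An `sm_fit`.
#' @param path Output path.
#' @param scaling Optional [scaling_config()] for physical conversion.
#' @param aic_table Optional [model_choice()] table.
#' @param ci Optional `sm_ci`.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, scaling = NULL, aic_table = NULL,
                             ci = NULL) {
  num <- function(x) formatC(x, digits = 12, format = "g")
  ln <- c(paste0("model\t", fit$spec$name),
          paste0("loglik\t", num(fit$loglik)),
          paste0("AIC\t", num(fit$AIC)),
          paste0("theta_hat\t", num(fit$theta_hat)),
          paste0("seed\t", fit$seed),
          paste0("mc_seed\t", fit$mc_seed),
          paste0("n_mc\t", fit$n_mc),
          paste0("scaled.", names(unclass(fit$params)), "\t",
                 num(as.double(fit$params))))
  if (!is.null(scaling)) {
    ph <- to_physical(fit$params, fit$theta_hat, scaling)
    ln <- c(ln, paste0("physical.", ph$parameter, "\t", num(ph$value),
                       "\t", ph$unit))
  }
  if (!is.null(aic_table))
    ln <- c(ln, "# AIC table",
            paste0("aic.", aic_table$model, "\t", num(aic_table$AIC),
                   "\tdelta=", num(aic_table$delta_AIC)))
  if (!is.null(ci))
    ln <- c(ln, "# 2.5-97.5% percentile CI",
            paste0("ci.", ci$ci$parameter, "\t", num(ci$ci$lower), "\t",
                   num(ci$ci$upper)))
  writeLines(ln, path)
  invisible(path)
}
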