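#' Pipeline configuration
#'
#' Collects the file paths, sample names and stage parameters of an
#' end-to-end run. Can also be loaded from a YAML file with
#' [readPipelineConfig()]; every argument here overrides the
#' corresponding YAML key.
#'
#' @param fasta,gff3,vcf input paths (required)
#' @param domains optional protein-domain TSV (gene_id, family,
#'   aa_start, aa_end)
#' @param prior_genes optional prior-knowledge gene list (one id or
#'   keyword per line)
#' @param samples the two sample names, contrast order (A, B)
#' @param out_dir output directory
#' @param scan see [scanParams()]
#' @param sv_filter see [svFilterParams()]
#' @param require_difference candidate filter setting
#' @param seed integer seed (recorded in the summary)
#' @return a validated config list
#' @export
pipelineConfig <- function(fasta, gff3, vcf, samples, out_dir,
                           domains = NULL, prior_genes = NULL,
                           scan = scanParams(),
                           sv_filter = svFilterParams(),
                           require_difference = FALSE, seed = 1L) {
  cfg <- list(fasta = fasta, gff3 = gff3, vcf = vcf, domains = domains,
              prior_genes = prior_genes, samples = samples,
              out_dir = out_dir, scan = scan, sv_filter = sv_filter,
              require_difference = require_difference, seed = seed)
  if (length(cfg$samples) != 2L)
    .stopf("config error: exactly two sample names required")
  for (key in c("fasta", "gff3", "vcf")) {
    if (is.null(cfg[[key]]))
      .stopf("config error: missing required path '%s'", key)
    if (!file.exists(cfg[[key]]))
      .stopf("config error: %s path does not exist: %s", key, cfg[[key]])
  }
  for (key in c("domains", "prior_genes"))
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      .stopf("config error: %s path does not exist: %s", key, cfg[[key]])
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with keys matching [pipelineConfig()]
#'   arguments (`scan` and `sv_filter` as nested maps)
#' @param ... overrides applied after the file is read
#' @return a validated config list
#' @export
readPipelineConfig <- function(path, ...) {
  y <- yaml::read_yaml(path)
  over <- list(...)
  y[names(over)] <- over
  y$scan <- do.call(scanParams, as.list(y$scan))
  y$sv_filter <- do.call(svFilterParams, as.list(y$sv_filter))
  do.call(pipelineConfig, y)
}

.stage_log <- function(stage, t0, detail)
  message(sprintf("[%s] %.2fs %s", stage, as.numeric(Sys.time()) - t0,
                  detail))

#' Run the full genome-contrast pipeline
#'
#' Stage order: ingest, sv-filter, annotate, contrast, scan, stats,
#' pfam, candidates. Every stage writes its table under
#' `config$out_dir`; a machine-readable `summary.json` and a
#' human-readable `report.md` close the run. Any stage error aborts
#' with the failing stage named. Deterministic given the inputs (the
#' pipeline itself draws no random numbers).
#'
#' @param config result of [pipelineConfig()] or [readPipelineConfig()]
#' @param skip character vector of stage names to skip among
#'   `"scan"`, `"pfam"`, `"candidates"`
#' @return the summary list, invisibly
#' @export
runPipeline <- function(config, skip = character(0)) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = config$seed, samples = config$samples)
  run_stage <- function(stage, expr) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(expr, error = function(e)
      .stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
    .stage_log(stage, t0, res$detail)
    res$value
  }

  ing <- run_stage("ingest", {
    genome <- readFasta(config$fasta)
    models <- readGeneModels(config$gff3)
    vs <- readVariants(config$vcf, config$samples)
    agree <- checkReferenceAgreement(vs, genome)
    list(value = list(genome = genome, models = models, vs = vs,
                      agree = agree),
         detail = sprintf("%d chroms, %d genes, %d variants (%d ref mismatches)",
                          length(genome), length(models), nVariants(vs),
                          agree$n_mismatch))
  })
  genome <- ing$genome; models <- ing$models
  summary$n_input_variants <- nVariants(ing$vs)
  summary$reference_mismatches <- ing$agree$n_mismatch

  vs <- run_stage("sv_filter", {
    fl <- filterSV(ing$vs, config$sv_filter)
    summary$sv_rejected <- nrow(fl$rejected)
    writeTsv(fl$rejected, file.path(config$out_dir, "sv_rejected.tsv"))
    list(value = fl$retained,
         detail = sprintf("%d records rejected", nrow(fl$rejected)))
  })

  effects <- run_stage("annotate", {
    eff <- annotateEffects(vs, models, genome)
    writeEffectTable(eff, file.path(config$out_dir, "effects.tsv"))
    list(value = eff,
         detail = sprintf("%d effect rows, %d coding",
                          nrow(eff), sum(eff$region_class == "genic_cds")))
  })
  summary$consequence_counts <-
    as.list(table(effects$consequence[effects$consequence != "none"]))

  contrasts <- run_stage("contrast", {
    ct <- contrastLoci(vs, config$samples[1], config$samples[2])
    writeTsv(cbind(variantTable(vs)[c("chrom", "pos", "ref", "alt")], ct),
             file.path(config$out_dir, "contrast.tsv"))
    cs <- contrastSummary(vs, config$samples[1], config$samples[2])
    summary$contrast <- cs
    list(value = ct,
         detail = sprintf("%d between-sample variants",
                          sum(ct$between_sample_variant)))
  })

  if (!"scan" %in% skip) {
    run_stage("scan", {
      chrlen <- chromLengths(genome)
      regions <- list()
      for (s in config$samples) {
        w <- scanHeterozygosity(vs, chrlen, s, config$scan)
        writeTsv(w, file.path(config$out_dir,
                              paste0("windows_", s, ".tsv")))
        regions[[s]] <- mergeHomozygousRegions(w)
        writeBed(regions[[s]],
                 file.path(config$out_dir, paste0("homozygous_", s, ".bed")))
      }
      diffs <- differentialRegions(regions[[1]], regions[[2]],
                                   config$samples[1], config$samples[2],
                                   min_width = config$scan$window_size)
      writeBed(stats::setNames(diffs, c("chrom", "start", "end", "name")),
               file.path(config$out_dir, "differential_regions.bed"))
      summary$scan <- list(
        n_regions = stats::setNames(
          vapply(regions, nrow, integer(1)), config$samples),
        n_differential = nrow(diffs))
      list(value = NULL,
           detail = sprintf("%d differential regions", nrow(diffs)))
    })
  }

  run_stage("stats", {
    vsum <- variationSummary(vs, chromLengths(genome), effects, models)
    summary$variation <- list(
      ts_tv = vsum$ts_tv$ratio,
      hom_fraction = lapply(vsum$per_sample, `[[`, "hom_fraction"),
      nonsyn_syn = lapply(vsum$nonsyn_syn, function(x) unname(x["ratio"])),
      region_density = vsum$region_density)
    writeTsv(vsum$indel_spectrum,
             file.path(config$out_dir, "indel_spectrum.tsv"))
    writeTsv(vsum$region_density,
             file.path(config$out_dir, "region_density.tsv"))
    list(value = NULL, detail = sprintf("Ts/Tv %.3f", vsum$ts_tv$ratio))
  })

  if (!"pfam" %in% skip && !is.null(config$domains)) {
    run_stage("pfam", {
      domains <- readDomainTable(config$domains)
      enr <- domainEnrichment(effects, domains)
      writeTsv(enr, file.path(config$out_dir, "pfam_enrichment.tsv"))
      summary$pfam <- list(n_families = nrow(enr),
                            n_flagged = sum(enr$flagged))
      list(value = NULL, detail = sprintf("%d families, %d flagged",
                                          nrow(enr), sum(enr$flagged)))
    })
  }

  if (!"candidates" %in% skip) {
    run_stage("candidates", {
      prior <- if (!is.null(config$prior_genes))
        readLines(config$prior_genes) else NULL
      cand <- selectCandidates(effects, vs, models, prior,
                               config$require_difference)
      writeTsv(cand, file.path(config$out_dir, "candidates.tsv"))
      writeBed(data.frame(chrom = cand$chrom, start = cand$start,
                          end = cand$start, name = cand$gene_id),
               file.path(config$out_dir, "candidates.bed"))
      pm <- physicalMapTable(cand)
      summary$candidates <- list(n = nrow(cand),
                                  per_chrom = as.list(pm$counts))
      list(value = NULL, detail = sprintf("%d candidate genes", nrow(cand)))
    })
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  .write_report(summary, file.path(config$out_dir, "report.md"))
  invisible(summary)
}

.write_report <- function(summary, path) {
  ln <- c("# Genome-contrast report", "",
          sprintf("Samples: %s vs %s", summary$samples[1],
                  summary$samples[2]),
          sprintf("Input variants: %d (SV rejected by filter: %d)",
                  summary$n_input_variants, summary$sv_rejected), "")
  if (!is.null(summary$variation)) {
    hf <- summary$variation$hom_fraction
    ln <- c(ln, "## Variation summary", "",
            sprintf("- Ts/Tv: %.3f", summary$variation$ts_tv),
            sprintf("- Homozygote fraction (SNP): %s",
                    paste(sprintf("%s %.3f", names(hf),
                                  vapply(hf, `[[`, 0, "SNP")),
                          collapse = ", ")), "")
  }
  if (!is.null(summary$scan))
    ln <- c(ln, "## Homozygosity scan", "",
            sprintf("- Differential regions: %d",
                    summary$scan$n_differential), "")
  if (!is.null(summary$pfam))
    ln <- c(ln, "## Pfam enrichment", "",
            sprintf("- Families tested: %d, flagged: %d",
                    summary$pfam$n_families, summary$pfam$n_flagged), "")
  if (!is.null(summary$candidates))
    ln <- c(ln, "## Candidate genes", "",
            sprintf("- Candidates: %d", summary$candidates$n), "")
  writeLines(ln, path)
  invisible(path)
}
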