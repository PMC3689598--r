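.config_keys <- list(
  top = c("seed", "out_dir", "genome", "genome_fasta", "mark_model", "stages",
          "protocols", "coverage", "error_rate", "use_adaptors", "qpcr_csv",
          "alpha"),
  genome = c("chromosome_lengths", "background_gc", "n_genes",
             "exons_per_gene", "exon_len", "intron_len", "promoter_len",
             "n_cpg_islands", "island_len", "island_gc", "satellite_monomer",
             "satellite_array_count", "satellite_array_len",
             "interspersed_repeat_classes"),
  mark_model = c("p_mC_cpg_island", "p_mC_cpg", "p_mC_chh", "p_hmC_cpg",
                 "p_hmC_chh_ctag", "repeat_multipliers", "stages"))

#' Load and validate a run configuration
#'
#' YAML file with sections `genome` (a [genome_spec()] parameter list) or a
#' `genome_fasta` path, `mark_model` ([mark_model()] parameters), the stage
#' and protocol lists, read simulation settings and an optional q-PCR CSV.
#' Unknown keys are rejected and referenced files must exist at load time.
#'
#' @param path YAML config path.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .config_keys$top)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  for (sec in c("genome", "mark_model")) {
    if (!is.null(cfg[[sec]])) {
      unknown <- setdiff(names(cfg[[sec]]), .config_keys[[sec]])
      if (length(unknown)) stop("unknown key(s) in section '", sec, "': ",
                                paste(unknown, collapse = ", "))
    }
  }
  if (is.null(cfg$genome) && is.null(cfg$genome_fasta)) {
    stop("config must provide either a 'genome' section or 'genome_fasta'")
  }
  for (pkey in c("genome_fasta", "qpcr_csv")) {
    if (!is.null(cfg[[pkey]]) && !file.exists(cfg[[pkey]])) {
      stop("configured file does not exist: ", pkey, " = ", cfg[[pkey]])
    }
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$stages <- cfg$stages %||% c("D7", "D12")
  cfg$protocols <- cfg$protocols %||% c("ME_RDA", "HME_RDA", "HELP_COCKTAIL")
  cfg$coverage <- as.integer(cfg$coverage %||% 3L)
  cfg$error_rate <- cfg$error_rate %||% 0
  cfg$alpha <- cfg$alpha %||% 0.05
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full simulation-and-analysis pipeline
#'
#' Executes genome simulation, methylome assignment per stage, library
#' simulation per protocol and stage, the read-to-site caller, annotation,
#' stage comparison and (when configured) the q-PCR analysis, writing every
#' artifact into `out_dir`. A single run seed fans out deterministically to
#' every stochastic step, so identical configurations produce byte-identical
#' artifacts. Inputs are never modified.
#'
#' @param config a `run_config` (or path to one).
#' @param out_dir output directory (created; overrides `config$out_dir`).
#' @return invisibly, a list with the run manifest and key in-memory results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("an output directory is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out_dir, ...)
  seed <- config$seed

  if (!is.null(config$genome)) {
    gargs <- config$genome
    gargs$chromosome_lengths <- unlist(gargs$chromosome_lengths)
    spec <- do.call(genome_spec, c(gargs,
                                   list(seed = derive_seed(seed, "genome"))))
    gen <- generate_genome(spec)
  } else {
    gen <- list(genome = read_fasta(config$genome_fasta),
                genes = data.frame(gene_id = character(), chrom = character(),
                                   start = integer(), end = integer(),
                                   strand = character()),
                exons = data.frame(gene_id = character(), chrom = character(),
                                   start = integer(), end = integer(),
                                   exon_number = integer()),
                repeats = data.frame(chrom = character(), start = integer(),
                                     end = integer(), class = character(),
                                     name = character()),
                islands = data.frame(chrom = character(), start = integer(),
                                     end = integer()))
  }
  chrom_lengths <- setNames(Biostrings::width(gen$genome), names(gen$genome))
  write_fasta(gen$genome, pth("genome.fa"))
  if (nrow(gen$genes)) write_gff3(gen$genes, gen$exons, pth("genes.gff3"))
  if (nrow(gen$repeats)) {
    write_bed(data.frame(chrom = gen$repeats$chrom, start = gen$repeats$start,
                         end = gen$repeats$end, name = gen$repeats$class),
              pth("repeats.bed"))
  }
  if (nrow(gen$islands)) {
    write_bed(gen$islands, pth("cpg_islands.bed"))
  }

  margs <- config$mark_model %||% list()
  if (!is.null(margs$repeat_multipliers)) {
    margs$repeat_multipliers <- unlist(margs$repeat_multipliers)
  }
  if (is.null(margs$stages)) {
    margs$stages <- setNames(rep(list(list()), length(config$stages)),
                             config$stages)
  }
  model <- do.call(mark_model, margs)

  manifest <- list(package = "methylsieve",
                   version = as.character(utils::packageVersion("methylsieve")),
                   seed = seed, stages = config$stages,
                   protocols = config$protocols,
                   coverage = config$coverage, error_rate = config$error_rate,
                   funnel = list())
  adaptors <- if (isTRUE(config$use_adaptors)) default_adaptors() else NULL
  tracks <- list(); all_sites <- list()
  for (stage in config$stages) {
    track <- assign_methylome(gen$genome, gen, model, stage,
                              seed = derive_seed(seed, stage))
    tracks[[stage]] <- track
    write_truth(track, pth(sprintf("truth_%s.tsv", stage)))
    for (protocol in config$protocols) {
      pconf <- protocol_config(protocol)
      frags <- if (protocol == "HELP_COCKTAIL") {
        simulate_help(gen$genome, track, pconf)
      } else simulate_rda(gen$genome, track, pconf)
      reads <- fragments_to_reads(gen$genome, frags,
                                  coverage = config$coverage,
                                  error_rate = config$error_rate,
                                  adaptors = adaptors, stage = stage,
                                  seed = derive_seed(seed,
                                                     paste(protocol, stage)))
      tag <- sprintf("%s_%s", tolower(protocol), stage)
      write_reads_fasta(reads, pth(sprintf("reads_%s.fa", tag)))
      cconf <- pipeline_config(protocol)
      res <- call_sites_pipeline(reads, gen$genome, cconf,
                                 adaptors = unlist(adaptors), stage = stage)
      write_funnel_report(res$report, pth(sprintf("funnel_%s.tsv", tag)))
      counts <- setNames(res$contigs$n_members, res$contigs$contig_id)
      write_sites_bed(res$sites, pth(sprintf("sites_%s.bed", tag)), counts)
      all_sites[[paste(protocol, stage)]] <- res$sites
      manifest$funnel[[tag]] <- as.list(res$report)
    }
  }

  sites <- do.call(rbind, all_sites)
  rownames(sites) <- NULL
  if (nrow(gen$genes) && nrow(sites)) {
    ann <- classify_regions(sites, gen$genes, gen$exons, chrom_lengths,
                            promoter_len = gen$spec$promoter_len %||% 5000L)
    utils::write.table(ann, pth("sites_annotated.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    base <- genomic_baseline(gen$genes, gen$exons, chrom_lengths,
                             promoter_len = gen$spec$promoter_len %||% 5000L)
    frtab <- data.frame(category = names(base), genomic = as.numeric(base),
                        library = as.numeric(attr(ann, "fractions")))
    utils::write.table(frtab, pth("region_fractions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  comp <- summarize_repeats(data.frame(chrom = sites$chrom,
                                       start = sites$pos,
                                       end = sites$pos + 1L),
                            gen$repeats, gen$islands)
  utils::write.table(
    data.frame(metric = c("n_sites", "n_with_repeat", "frac_with_repeat",
                          paste0("base_frac_", names(comp$class_base_fraction)),
                          "n_in_island", "frac_in_island"),
               value = c(comp$n_sequences, comp$n_with_repeat,
                         comp$frac_with_repeat, comp$class_base_fraction,
                         comp$n_in_island, comp$frac_in_island)),
    pth("composition.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_bedgraph(coverage_bins(sites, chrom_lengths,
                               bin_bp = max(1000L, min(chrom_lengths) %/% 20L)),
                 pth("site_coverage.bedgraph"))

  overlaps <- list()
  if (length(config$stages) == 2L) {
    for (protocol in config$protocols) {
      a <- all_sites[[paste(protocol, config$stages[1])]]
      b <- all_sites[[paste(protocol, config$stages[2])]]
      cmp <- compare_site_sets(a, b, by = "position")
      overlaps[[protocol]] <- data.frame(
        protocol = protocol, only_stage1 = cmp$n_only_a,
        shared = cmp$n_shared, only_stage2 = cmp$n_only_b)
    }
    utils::write.table(do.call(rbind, overlaps), pth("stage_overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(config$qpcr_csv)) {
    est <- resistance(read_qpcr(config$qpcr_csv))
    verdicts <- compare_stages(est, alpha = config$alpha)
    utils::write.table(verdicts, pth("qpcr_verdicts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(out_dir = out_dir, manifest = manifest, sites = sites,
                 genome = gen, tracks = tracks))
}
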