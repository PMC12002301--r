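# Orchestration: discovery (ORFs -> grammar -> ranking -> families) and
# orthology evidence (conserved columns + clade membership + shared
# introns), with a single config object holding every tunable threshold.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the discovery/orthology pipeline
#' with its default. Defaults follow the screen this pipeline implements:
#' candidates are ranked and the top 5000 retained; families require 4 of
#' 6 identical terminal residues; trees use 1000 bootstrap replicates.
#'
#' @param min_orf_aa minimum ORF length (residues) before annotation.
#' @param dibasic allowed basic pairs.
#' @param allow_monobasic also cleave at single R.
#' @param min_len,max_len mature peptide length filter.
#' @param motif family motif pattern.
#' @param top_k candidates retained after ranking.
#' @param terminus,k,m family clustering parameters.
#' @param min_b "several" threshold for conserved columns.
#' @param boot_reps bootstrap replicates.
#' @param anchor_k,min_intron,max_intron spliced-alignment parameters.
#' @param tol_ppm MS match tolerance.
#' @param seed integer seed for stochastic stages.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_orf_aa = 60L, dibasic = c("KR", "RR"),
                            allow_monobasic = FALSE, min_len = 5L,
                            max_len = 40L, motif = "GPxxG", top_k = 5000L,
                            terminus = "C", k = 6L, m = 4L, min_b = 3L,
                            boot_reps = 1000L, anchor_k = 12L,
                            min_intron = 30L, max_intron = 100000L,
                            tol_ppm = 10, seed = 1L) {
  cfg <- list(min_orf_aa = as.integer(min_orf_aa), dibasic = dibasic,
              allow_monobasic = allow_monobasic, min_len = as.integer(min_len),
              max_len = as.integer(max_len), motif = motif,
              top_k = as.integer(top_k), terminus = terminus,
              k = as.integer(k), m = as.integer(m), min_b = as.integer(min_b),
              boot_reps = as.integer(boot_reps), anchor_k = as.integer(anchor_k),
              min_intron = as.integer(min_intron),
              max_intron = as.integer(max_intron), tol_ppm = tol_ppm,
              seed = as.integer(seed))
  stopifnot(all(cfg$dibasic %in% c("KR", "RR", "KK", "RK")),
            cfg$min_len <= cfg$max_len, cfg$m >= 1L, cfg$m <= cfg$k,
            cfg$min_b >= 2L, cfg$boot_reps >= 1L, cfg$top_k >= 1L,
            cfg$tol_ppm > 0)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path file path.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for config files")
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for config files")
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the discovery stage
#'
#' Chains sequence input, (optionally) six-frame ORF extraction, the
#' processing-grammar annotator with score ranking, and terminal-residue
#' family clustering.
#'
#' @param input a FASTA path or a [seq_records()] data frame.
#' @param config a [pipeline_config()].
#' @param alphabet `"protein"` (records are candidate proteins) or
#'   `"dna"` (six-frame ORFs are extracted first).
#' @return list with `candidates` (ranked annotation table), `peptides`,
#'   `families`, and `provenance` (record counts surviving each stage,
#'   config, package version).
#' @export
run_discovery <- function(input, config = pipeline_config(),
                          alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  records <- if (is.character(input)) read_fasta(input, alphabet) else input
  if (!nrow(records)) stop("empty input")
  n_input <- nrow(records)
  if (alphabet == "dna") {
    orfs <- do.call(rbind, lapply(seq_len(nrow(records)), function(i)
      six_frame_orfs(records$residues[i], min_aa = config$min_orf_aa,
                     parent_id = records$id[i])))
    if (is.null(orfs) || !nrow(orfs)) stop("no ORFs >= ", config$min_orf_aa,
                                           " aa in the input")
    records <- seq_records(
      id = sprintf("%s|%+d|%d-%d", orfs$parent_id, orfs$frame,
                   orfs$nt_start, orfs$nt_end),
      residues = orfs$protein)
  }
  n_candidates <- nrow(records)
  ann <- annotate_set(records, top_k = config$top_k, motif = config$motif,
                      dibasic = config$dibasic,
                      allow_monobasic = config$allow_monobasic,
                      min_len = config$min_len, max_len = config$max_len)
  fams <- if (nrow(ann$peptides))
    cluster_families(ann$peptides, terminus = config$terminus,
                     k = config$k, m = config$m) else list()
  list(candidates = ann$annotations, peptides = ann$peptides,
       families = fams,
       provenance = list(
         n_input = n_input, n_candidates = n_candidates,
         n_ranked = nrow(ann$annotations), n_peptides = nrow(ann$peptides),
         n_families = length(fams), config = unclass(config),
         package_version = as.character(utils::packageVersion("bombemine"))))
}

#' Run the orthology-evidence stage
#'
#' Combines three evidence lines for a query precursor: (i) group-aware
#' conserved alignment columns, (ii) clade membership with the reference
#' group in a bootstrap-supported NJ tree, (iii) shared intron
#' position/phase on the protein alignment.
#'
#' @param records a [seq_records()] data frame of precursor proteins with
#'   `group` tags; one group must be the outgroup.
#' @param query id of the query precursor.
#' @param gene_pairs optional named list (by record id) of lists with
#'   `cdna`, `genomic`, `cds_offset`, `cds_len` for the gene-structure
#'   evidence line.
#' @param reference_group,query_group,outgroup_group group tags.
#' @param config a [pipeline_config()].
#' @return list with `msa`, `conserved`, `tree` (with bootstrap
#'   supports), `clade`, `introns`, and a one-row `evidence` data frame
#'   (`conserved_ok`, `clade_ok`, `intron_ok`).
#' @export
run_orthology <- function(records, query, gene_pairs = NULL,
                          reference_group = "chordate",
                          query_group = "echinoderm",
                          outgroup_group = "outgroup",
                          config = pipeline_config()) {
  stopifnot(query %in% records$id)
  groups <- records$group
  out_ids <- records$id[groups == outgroup_group]
  ref_ids <- records$id[groups == reference_group]
  qgrp_ids <- records$id[groups == query_group]
  if (!length(out_ids)) stop("no outgroup records (group '", outgroup_group, "')")
  if (!length(ref_ids)) stop("no reference records (group '", reference_group, "')")

  msa <- progressive_msa(records)
  conserved <- conserved_columns(msa, group_a_ids = qgrp_ids,
                                 group_b_ids = ref_ids, min_b = config$min_b)
  # the query must itself carry most of the group-conserved residues
  qrow <- strsplit(msa$rows[match(query, msa$ids)], "")[[1]]
  conserved_ok <- nrow(conserved) > 0 &&
    mean(qrow[conserved$column] == conserved$residue) >= 0.5

  bs <- bootstrap_support(msa, n_reps = config$boot_reps, seed = config$seed,
                          return_trees = TRUE)
  # contrast leaves: everything outside query group, reference group and
  # outgroup (i.e. non-orthologous families such as CCHa/EP- or ET-type)
  contrast <- records$id[!groups %in% c(query_group, reference_group,
                                        outgroup_group)]
  clade <- is_in_clade_with(bs$tree, query, ref_ids, out_ids,
                            contrast_leaves = contrast)
  # clade membership is only claimed on a well-supported node
  clade_support <- split_support(bs$trees, clade$clade_leaves)
  clade_ok <- clade$in_clade && (is.na(clade_support) || clade_support >= 0.9)

  introns <- NULL; intron_ok <- NA
  if (!is.null(gene_pairs) && length(gene_pairs) >= 2L) {
    models <- lapply(names(gene_pairs), function(sp) {
      gp <- gene_pairs[[sp]]
      spliced_align(gp$cdna, gp$genomic, anchor_k = config$anchor_k,
                    min_intron = config$min_intron,
                    max_intron = config$max_intron,
                    cds_offset = gp$cds_offset, cds_len = gp$cds_len,
                    genomic_id = sp)
    })
    names(models) <- names(gene_pairs)
    introns <- map_introns_to_alignment(models, msa)
    qi <- introns[introns$species == query, , drop = FALSE]
    ref_in <- introns[introns$species %in% ref_ids, , drop = FALSE]
    intron_ok <- nrow(qi) > 0 && nrow(ref_in) > 0 &&
      any(paste(qi$column, qi$phase) %in% paste(ref_in$column, ref_in$phase))
  }
  list(msa = msa, conserved = conserved, tree = bs$tree, support = bs$support,
       clade = clade, clade_support = clade_support, introns = introns,
       evidence = data.frame(query = query, conserved_ok = conserved_ok,
                             clade_ok = clade_ok,
                             intron_ok = intron_ok))
}
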