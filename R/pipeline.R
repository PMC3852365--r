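## End-to-end orchestration: simulate -> pcr -> classify -> consensus ->
## annotate -> context -> rbip, with per-stage artifacts and a summary
## report.  Stages communicate via files so each can be run standalone.

#' Pipeline configuration
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param genome_size Background size in bp.
#' @param families Named list of [family_spec()]; default the built-in nine.
#' @param divergence Per-copy substitution rate.
#' @param n_accessions Accessions used for clone isolation.
#' @param clones_per_accession RT clones sampled per accession for the main
#'   (F) primer set; the first two accessions are additionally amplified
#'   with V and H.
#' @param family_cut Single-linkage family threshold (peptide p-distance).
#' @param rbip_accessions,rbip_absent Panel size and number of accessions
#'   carrying the empty allele at the chosen marker locus.
#' @param out Output directory.
#' @export
pipeline_config <- function(seed = 7L, genome_size = 2e6,
                            families = copia_families(), divergence = 0.05,
                            n_accessions = 5L, clones_per_accession = 10L,
                            family_cut = 0.40, rbip_accessions = 12L,
                            rbip_absent = 2L, out = tempfile("copiascan_run_")) {
  structure(list(seed = as.integer(seed), genome_size = genome_size,
                 families = families, divergence = divergence,
                 n_accessions = as.integer(n_accessions),
                 clones_per_accession = as.integer(clones_per_accession),
                 family_cut = family_cut,
                 rbip_accessions = as.integer(rbip_accessions),
                 rbip_absent = as.integer(rbip_absent), out = out),
            class = "pipeline_config")
}

#' Run the full discovery pipeline on a simulated genome
#'
#' Simulates a genome with implanted copies of every configured family,
#' isolates RT clones by degenerate-primer in-silico PCR across accessions,
#' classifies them into families (NJ tree + single-linkage cut + chi-square
#' homogeneity test), rebuilds each family's full-length consensus by
#' iterative extension, annotates its structure, profiles genomic context,
#' designs an RBIP marker at a recent insertion and genotypes an accession
#' panel.  Artifacts are written under `config$out`; a summary report
#' compares every recovered quantity against simulation truth.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list (also written as JSON).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, stages = list())
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch({
      t <- system.time(val <- force(expr))["elapsed"]
      report$stages[[name]] <<- list(status = "ok", seconds = round(t, 2))
      message(sprintf("[%s] ok (%.1fs)", name, t))
      val
    }, error = function(e) {
      report$stages[[name]] <<- list(status = "error",
                                     message = conditionMessage(e))
      message(sprintf("[%s] ERROR: %s", name, conditionMessage(e)))
      NULL
    })
  }

  ## -- simulate ------------------------------------------------------------
  sim <- stage("simulate", {
    templates <- lapply(seq_along(config$families), function(i)
      build_family_template(config$families[[i]],
                            seed = derive_seed(config$seed, i)))
    names(templates) <- names(config$families)
    genome <- new_genome(config$genome_size,
                         seed = derive_seed(config$seed, 0))
    for (i in seq_along(templates)) {
      n <- config$families[[i]]$target_copies
      ## one recent (zero-divergence, identical-LTR) copy per family: the
      ## RBIP marker substrate; the rest diverge at the configured rate
      genome <- implant_copies(genome, templates[[i]], n = 1,
                               divergence = 0,
                               seed = derive_seed(config$seed, 150 + i))
      if (n > 1)
        genome <- implant_copies(genome, templates[[i]], n = n - 1L,
                                 divergence = config$divergence,
                                 seed = derive_seed(config$seed, 100 + i))
    }
    if (nrow(genome$elements))
      genome <- plant_genes(genome, config$families,
                            seed = derive_seed(config$seed, 200))
    write_genome(genome, out, "genome")
    list(genome = genome, templates = templates)
  })
  if (is.null(sim)) return(finish_report(report, out))
  genome <- sim$genome

  ## -- pcr + clone isolation ----------------------------------------------
  clones <- stage("pcr", {
    accs <- paste0("acc", seq_len(config$n_accessions))
    all_clones <- list()
    for (ai in seq_along(accs)) {
      sets <- if (ai <= 2) c("F", "V", "H") else "F"
      for (sn in sets) {
        amp <- amplify(genome, rt_primer_set(sn))
        if (!nrow(amp)) next
        k <- min(nrow(amp), config$clones_per_accession)
        pick <- with_seed(derive_seed(config$seed, 300 + 10 * ai + match(sn, c("F","V","H"))),
                          sample.int(nrow(amp), k))
        sub <- amp[pick, , drop = FALSE]
        cl <- clones_from_amplicons(sub, accs[ai])
        ## ground truth family of each clone via its genomic origin (clone
        ## ids index into `sub`; the RT filter may have dropped some)
        if (nrow(cl)) {
          idx <- as.integer(sub("^.*_", "", cl$id))
          cl$truth_family <- vapply(idx, function(p) {
            hit <- genome$elements$start <= sub$start[p] &
              genome$elements$end >= sub$end[p] &
              genome$elements$contig == sub$contig[p]
            if (any(hit)) genome$elements$family[which(hit)[1]] else NA_character_
          }, "")
          all_clones[[length(all_clones) + 1L]] <- cl
        }
      }
    }
    cl <- do.call(rbind, all_clones)
    if (is.null(cl) || !nrow(cl)) {
      message("pcr: no clones amplified")
      cl <- clones_from_amplicons(amplify(new_genome(1000, 1),
                                          rt_primer_set("F")))
      cl$truth_family <- character(0)
    }
    utils::write.csv(cl[, setdiff(names(cl), "nt")],
                     file.path(out, "clones.csv"), row.names = FALSE)
    cl
  })

  ## -- classify ------------------------------------------------------------
  classification <- NULL
  if (!is.null(clones) && nrow(clones) >= 3) {
    classification <- stage("classify", {
      ## drop duplicate amplicons (same nt) across accessions for the tree
      block <- trim_to_core(clones)
      d <- p_distance_matrix(block)
      tree <- neighbor_joining(d)
      ape::write.tree(tree, file.path(out, "clones.nwk"))
      fams <- cut_families(d, config$family_cut)
      counts <- table(clones$accession, fams$families[clones$id])
      chi <- tryCatch(family_distribution_test(counts),
                      error = function(e) list(error = conditionMessage(e)))
      list(families = fams, tree = tree, counts = counts, chi = chi)
    })
  } else {
    report$stages[["classify"]] <- list(status = "skipped",
                                        message = "fewer than 3 clones")
    message("[classify] skipped: no clones")
  }

  ## -- consensus + annotate -----------------------------------------------
  annotations <- NULL
  if (!is.null(classification)) {
    annotations <- stage("consensus_annotate", {
      fams <- classification$families$families
      anns <- list(); seqs <- character(); lineages <- character()
      refs <- lineage_references()
      for (fam in unique(fams)) {
        ids <- names(fams)[fams == fam]
        fc <- clones[clones$id %in% ids & clones$primer_set == "F", ]
        if (!nrow(fc)) next
        seed_rt <- seed_consensus(fc$nt[nchar(fc$nt) == max(nchar(fc$nt))])
        st <- tryCatch(
          iterative_extend(seed_rt, genome),
          error = function(e) { message(sprintf("  %s: %s", fam,
                                                conditionMessage(e))); NULL })
        if (is.null(st)) next
        ann <- tryCatch(annotate_element(st$consensus),
                        error = function(e) NULL)
        if (is.null(ann)) next
        anns[[fam]] <- ann
        seqs[[fam]] <- st$consensus
        core <- rt_core_peptide(ann)
        lineages[[fam]] <- if (is.null(core)) "unassigned" else
          with_seed(derive_seed(config$seed, 400 + length(anns)),
                    assign_lineage(core, refs)$lineage)
      }
      if (length(anns)) {
        tab <- structural_table(anns, seqs, lineages)
        utils::write.csv(tab, file.path(out, "structural_table.csv"),
                         row.names = FALSE)
        Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(seqs)),
                                    file.path(out, "consensus.fa"))
        list(annotations = anns, seqs = seqs, table = tab)
      } else NULL
    })
  }

  ## -- context -------------------------------------------------------------
  context <- stage("context", {
    prof <- context_profiles(genome)
    rep_ <- withCallingHandlers(family_context_report(prof),
                                warning = function(w) invokeRestart("muffleWarning"))
    utils::write.csv(prof, file.path(out, "context_profiles.csv"),
                     row.names = FALSE)
    if (!is.null(rep_))
      utils::write.csv(rep_, file.path(out, "context_report.csv"),
                       row.names = FALSE)
    list(profiles = prof, report = rep_)
  })

  ## -- rbip ----------------------------------------------------------------
  rbip <- stage("rbip", {
    recent <- find_recent_insertions(genome)
    if (!nrow(recent)) stop("no recent insertions found")
    marker <- NULL
    for (i in seq_len(nrow(recent))) {
      marker <- tryCatch(design_marker(genome, recent[i, ]),
                         error = function(e) NULL)
      if (!is.null(marker)) break
    }
    if (is.null(marker)) stop("no designable RBIP locus")
    accs <- paste0("acc", seq_len(config$rbip_accessions))
    presence <- matrix(TRUE, config$rbip_accessions, 1,
                       dimnames = list(accs, marker$locus))
    if (config$rbip_absent > 0)
      presence[seq_len(config$rbip_absent), 1] <- FALSE
    panel <- simulate_accessions(genome, presence)
    calls <- genotype_panel(panel, marker)
    writeLines(gel_schematic(calls, marker), file.path(out, "rbip_gel.txt"))
    utils::write.csv(calls, file.path(out, "rbip_calls.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(locus = marker$locus, family = marker$family,
                              tsd = marker$tsd,
                              expected = as.list(marker$expected)),
                         file.path(out, "rbip_marker.json"),
                         auto_unbox = TRUE)
    list(marker = marker, presence = presence, calls = calls)
  })

  ## -- report ---------------------------------------------------------------
  truth_fams <- unique(genome$elements$family)
  report$summary <- list(
    n_families_truth = length(truth_fams),
    n_families_recovered = if (!is.null(classification))
      classification$families$n_families else NA,
    chi_square = if (!is.null(classification)) classification$chi else NULL,
    n_consensus = if (!is.null(annotations)) length(annotations$annotations) else 0L,
    structural_match = if (!is.null(annotations))
      structural_match_rate(annotations$table, config$families) else NA,
    genotype_concordance = if (!is.null(rbip))
      mean((rbip$calls$call == "occupied") == rbip$presence[, 1]) else NA,
    elapsed_seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1))
  finish_report(report, out)
}

## Fraction of recovered consensus rows whose (total_len, ltr_len,
## gagpol_aa) match some configured family exactly.
structural_match_rate <- function(tab, families) {
  if (is.null(tab) || !nrow(tab)) return(NA)
  truth <- do.call(rbind, lapply(families, function(f)
    c(f$total_len, f$ltr_len, f$gagpol_len)))
  mean(vapply(seq_len(nrow(tab)), function(i)
    any(truth[, 1] == tab$total_len[i] & truth[, 2] == tab$ltr_len[i] &
        truth[, 3] == tab$gagpol_aa[i]), TRUE))
}

finish_report <- function(report, out) {
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  for (s in names(x$stages))
    cat(sprintf("  %-18s %s\n", s, x$stages[[s]]$status))
  if (!is.null(x$summary)) {
    cat(sprintf("  families: %s recovered / %s implanted\n",
                x$summary$n_families_recovered, x$summary$n_families_truth))
    cat(sprintf("  structural parameter match: %s\n",
                format(x$summary$structural_match)))
    cat(sprintf("  genotype concordance: %s\n",
                format(x$summary$genotype_concordance)))
  }
  invisible(x)
}

## RT-core peptide (from the TAFLHG entry motif, 220 aa) of an annotated
## element; NULL when the motif is absent.
rt_core_peptide <- function(ann) {
  pep <- ann$orf$peptide
  if (!nchar(pep)) return(NULL)
  at <- find_peptide_motif(pep, RT_MOTIF_ENTRY, 1L)
  if (is.na(at) || at + RT_CORE_LEN_AA - 1L > nchar(pep)) return(NULL)
  substr(pep, at, at + RT_CORE_LEN_AA - 1L)
}
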