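# End-to-end workflow: classify genes, compute composition profiles, run the
# internal decomposition by gene type and by GC3/expression bands, the
# ENC-plot and neutrality-plot diagnostics, and the two resampling
# procedures, writing a TSV/JSON report bundle.

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full codon usage analysis pipeline
#'
#' Executes catalog loading (or synthetic generation), classification,
#' per-gene metrics, internal correspondence analysis by gene type and by
#' GC3 and expression bands, ENC-plot and neutrality-plot diagnostics, and
#' the subsampling and label-permutation tests, writing all reports under
#' `out_dir`. Outputs are deterministic given `seed`.
#'
#' @param fasta_path,gff_path input genome and annotation; ignored when
#'   `synthetic` is a [synthetic_config()] (the inputs are then generated
#'   under `out_dir/input`).
#' @param expression optional data.frame (`gene_id`, `expression`) for the
#'   expression-band decomposition; generated automatically for synthetic
#'   runs.
#' @param synthetic optional [synthetic_config()] requesting synthetic
#'   input.
#' @param config a [catalog_config()].
#' @param gc3_thresholds band boundaries for the GC3 grouping.
#' @param n_iter resampling iterations.
#' @param seed integer seed for the resampling procedures.
#' @param out_dir output directory.
#' @return invisibly, a list with the catalog, profiles, decompositions,
#'   diagnostics, resampling results and file paths.
#' @export
run_pipeline <- function(fasta_path = NULL, gff_path = NULL,
                         expression = NULL, synthetic = NULL,
                         config = catalog_config(),
                         gc3_thresholds = c(0.8, 0.7, 0.6, 0.5),
                         n_iter = 1000L, seed = 1L,
                         out_dir = "codonica-out") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(synthetic)) {
    sim <- simulate_catalog(synthetic, file.path(out_dir, "input"))
    fasta_path <- sim$fasta; gff_path <- sim$gff3
    if (is.null(expression)) {
      expression <- simulate_expression(sim$truth, synthetic)
    }
  }
  if (is.null(fasta_path) || is.null(gff_path)) {
    stop("either fasta_path + gff_path or a synthetic config is required",
         call. = FALSE)
  }

  catalog <- load_catalog(fasta_path, gff_path, config)
  rec <- catalog$records
  stage_log("classify", "%d genes: %d SEG, %d MEG, %d excluded",
            nrow(rec), sum(rec$label == "SEG"), sum(rec$label == "MEG"),
            sum(rec$label == "EXCLUDED"))
  paths <- write_catalog(catalog, out_dir)

  profiles <- composition_profiles(catalog)
  stage_log("metrics", "profiles for %d retained genes", nrow(profiles))
  paths["profiles"] <- write_profiles(profiles,
                                      file.path(out_dir, "profiles.tsv"))
  counts <- attr(profiles, "counts")

  decompositions <- list()
  tab_type <- build_table(counts, profiles$label)
  decompositions$gene_type <- ica_decompose(tab_type)
  gc3_groups <- make_groups(profiles$gc3, gc3_thresholds)
  decompositions$gc3 <- ica_decompose(build_table(counts, gc3_groups$group))
  if (!is.null(expression)) {
    expr <- expression$expression[match(profiles$gene_id,
                                        expression$gene_id)]
    expr_groups <- make_groups(expr, thresholds = NULL,
                               matched_sizes = gc3_groups$sizes)
    decompositions$expression <-
      ica_decompose(build_table(counts, expr_groups$group))
  }
  for (nm in names(decompositions)) {
    p <- file.path(out_dir, sprintf("ica_%s.json", nm))
    write_ica_report(decompositions[[nm]], p)
    paths[paste0("ica_", nm)] <- p
    stage_log("ica", "%s: between-class synonymous %.3f%% of total inertia",
              nm, decompositions[[nm]]$percentages[["bw"]])
  }

  diag <- list(
    enc_plot = enc_plot(profiles$enc, profiles$gc3s, profiles$label),
    neutrality = lapply(split(profiles, profiles$label), function(d)
      neutrality_fit(d$gc12, d$gc3)))
  seg <- profiles[profiles$label == "SEG", ]
  meg <- profiles[profiles$label == "MEG", ]
  diag$slope_comparison <- compare_slopes(seg$gc3, seg$gc12,
                                          meg$gc3, meg$gc12)
  diag_path <- file.path(out_dir, "diagnostics.json")
  jsonlite::write_json(list(
    enc_plot_fits = diag$enc_plot$fits,
    neutrality = lapply(diag$neutrality, function(f)
      list(slope = f$slope, intercept = f$intercept, r = f$r,
           p = f$p_value, n = f$n)),
    slope_comparison = diag$slope_comparison),
    diag_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths["diagnostics"] <- diag_path
  stage_log("diagnostics", "neutrality slopes: %s",
            paste(sprintf("%s %.3f", names(diag$neutrality),
                          vapply(diag$neutrality, `[[`, 1, "slope")),
                  collapse = ", "))

  resampling <- list(
    subsample = subsample_null(tab_type, n_iter = n_iter, seed = seed),
    label_permutation = label_permutation(tab_type, n_iter = n_iter,
                                          seed = seed + 1L))
  for (nm in names(resampling)) {
    p <- file.path(out_dir, sprintf("resampling_%s.json", nm))
    write_permutation_report(resampling[[nm]], p)
    paths[paste0("resampling_", nm)] <- p
    stage_log("resample", "%s: observed %.3f%%, null %.4f%% +/- %.4f%%",
              nm, resampling[[nm]]$observed, resampling[[nm]]$mean,
              resampling[[nm]]$sd)
  }

  invisible(list(catalog = catalog, profiles = profiles,
                 decompositions = decompositions, diagnostics = diag,
                 resampling = resampling, paths = paths))
}
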