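#' Configuration for an end-to-end pipeline run
#'
#' Collects the inputs and analysis options for [run_pipeline()]. Inputs may
#' be in-memory objects or file paths (paths are read with the package
#' readers). A seed is required: every stochastic step (GSEA permutations and
#' tie-breaks) derives its stream from it, so a config reruns bit-identically.
#'
#' @param plate A [plate_timeseries()] or path to a long-form plate export.
#' @param plate_map Path to the plate map CSV (required when `plate` is a
#'   path).
#' @param library A [biomarker_library()] or path to a library TSV.
#' @param term_map Term map list or path to a `term,orf` TSV; `NULL` derives
#'   it from the library annotations.
#' @param references Reference-compound response tibble (columns `compound,
#'   category, concentration_mg_L, peli`) or path to such a CSV; `NULL`
#'   skips toxic equivalents.
#' @param ros,comet,h2o2_standard Optional phenotype inputs (tibbles or CSV
#'   paths); `NULL` skips the phenotype stage.
#' @param out_dir Output directory; `NULL` runs in memory only.
#' @param threshold Toxicity positivity threshold (> 1).
#' @param aggregate PELI aggregation method, see [peli_aggregate()].
#' @param peli_fun Single-ORF PELI strategy, see [peli_orf()].
#' @param drift_correct Housekeeping drift correction flag.
#' @param od_floor,p_floor Normalization floors, see
#'   [normalize_expression()].
#' @param c_range Studied concentration range for 4PL fitting and censoring.
#' @param n_perm GSEA permutation count.
#' @param seed Integer root seed (required).
#' @param linkage Clustering linkage, see [cluster_profiles()].
#' @param p_adjust Ontology-enrichment correction, see
#'   [ontology_enrichment()].
#' @return A `run_config` list.
#' @export
run_config <- function(plate, plate_map = NULL, library, term_map = NULL,
                       references = NULL, ros = NULL, comet = NULL,
                       h2o2_standard = NULL, out_dir = NULL,
                       threshold = 1.5, aggregate = "geometric",
                       peli_fun = peli_orf, drift_correct = TRUE,
                       od_floor = 0.01, p_floor = 1e-6,
                       c_range = c(0.031, 32), n_perm = 1000, seed,
                       linkage = "average", p_adjust = "none") {
  if (missing(seed)) abort("run_config requires a seed")
  if (threshold <= 1) abort("threshold must exceed 1")
  structure(
    list(plate = plate, plate_map = plate_map, library = library,
         term_map = term_map, references = references, ros = ros,
         comet = comet, h2o2_standard = h2o2_standard, out_dir = out_dir,
         threshold = threshold, aggregate = aggregate, peli_fun = peli_fun,
         drift_correct = drift_correct, od_floor = od_floor,
         p_floor = p_floor, c_range = c_range, n_perm = n_perm,
         seed = as.integer(seed), linkage = linkage, p_adjust = p_adjust),
    class = "run_config"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)))
  })
}

resolve_table <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) reader(x) else x
}

config_settings <- function(config) {
  list(threshold = config$threshold, aggregate = config$aggregate,
       drift_correct = config$drift_correct, od_floor = config$od_floor,
       p_floor = config$p_floor, c_range = config$c_range,
       n_perm = config$n_perm, seed = config$seed,
       linkage = config$linkage, p_adjust = config$p_adjust,
       peli_strategy = if (identical(config$peli_fun, peli_orf))
         "exp_time_averaged_abs_ln_i" else "custom")
}

config_hash <- function(settings) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(settings, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the end-to-end toxicogenomic analysis
#'
#' Executes induction -> PELI -> concentration-response (+ toxic
#' equivalents) -> enrichment -> multivariate -> phenotype correlation, and
#' (when `out_dir` is set) writes tidy result tables, a summary table with
#' censored PELI1.5 rendering ("N/A", "<c_min"), Newick dendrograms, and a
#' JSON manifest recording the package version, config hash, seed, and every
#' analysis setting in effect. Any stage failure aborts with the stage name.
#'
#' @param config A [run_config()].
#' @return List of results: `profiles`, `peli`, `profile_matrix`, `fits`,
#'   `endpoints`, `summary`, `gsea`, `ontology`, `clustering`, `pca`,
#'   `phenotype`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  library <- run_stage("inputs", {
    lib <- resolve_table(config$library, read_library)
    lib
  })
  pts <- run_stage("inputs", {
    if (is.character(config$plate)) {
      if (is.null(config$plate_map)) {
        abort("plate given as a path but no plate_map path supplied")
      }
      read_plate_export(config$plate, read_plate_map(config$plate_map))
    } else config$plate
  })
  run_stage("inputs", validate_layout_library(
    pts$layout[pts$layout$role %in% c("reporter", "vehicle_control"), ],
    library))
  term_map <- run_stage("inputs", {
    tm <- resolve_table(config$term_map, read_term_map)
    tm %||% term_map_from_library(library)
  })
  references <- run_stage("inputs", resolve_table(
    config$references, function(p) readr::read_csv(p, show_col_types = FALSE)))

  norm <- run_stage("normalize", normalize_expression(
    pts, od_floor = config$od_floor, p_floor = config$p_floor))
  profiles <- run_stage("induction", induction_profiles(
    norm, drift_correct = config$drift_correct, p_floor = config$p_floor,
    hk_orf = attr(pts$layout, "hk_orf") %||% "PGK1"))
  peli_tab <- run_stage("peli", peli_table(
    profiles, library, method = config$aggregate,
    peli_fun = config$peli_fun))
  mat <- run_stage("peli", profile_matrix(profiles))

  dr <- run_stage("dose_response", fit_dose_response(
    peli_tab, references, config))

  gsea <- run_stage("enrichment", gsea_all_conditions(
    peli_tab, library, n_perm = config$n_perm, seed = config$seed))
  top_c <- max(peli_tab$concentration_mg_L)
  ontology <- run_stage("enrichment", {
    rows <- lapply(unique(peli_tab$compound), function(cp) {
      hits <- activated_orfs(peli_tab, cp, top_c, config$threshold)
      res <- ontology_enrichment(hits, library, term_map,
                                 p_adjust = config$p_adjust)
      if (nrow(res) > 0) res$compound <- cp
      res
    })
    dplyr::bind_rows(rows)
  })

  clustering <- run_stage("multivariate", list(
    conditions = cluster_profiles(mat, "columns", config$linkage),
    biomarkers = cluster_profiles(mat, "rows", config$linkage)
  ))
  pca <- run_stage("multivariate", pca_profiles(mat))

  phenotype <- run_stage("phenotype", phenotype_stage(peli_tab, config))

  manifest <- list(
    package = "pelitox",
    version = as.character(utils::packageVersion("pelitox")),
    seed = config$seed,
    settings = config_settings(config)
  )
  manifest$config_hash <- config_hash(manifest$settings)

  results <- list(profiles = profiles, peli = peli_tab,
                  profile_matrix = mat, fits = dr$fit_table,
                  fit_objects = dr$fits, ref_fits = dr$ref_fits,
                  endpoint_objects = dr$endpoint_objects,
                  endpoints = dr$endpoints, summary = dr$summary,
                  gsea = gsea, ontology = ontology, clustering = clustering,
                  pca = pca, phenotype = phenotype, manifest = manifest)
  if (!is.null(config$out_dir)) {
    run_stage("write", write_pipeline_outputs(results, config$out_dir))
  }
  results
}

# 4PL fits per (compound x category/total), PELI1.5 endpoints with
# censoring, and toxic equivalents against the reference compounds.
fit_dose_response <- function(peli_tab, references, config) {
  agg <- peli_tab[peli_tab$level %in% c("category", "total"), , drop = FALSE]
  compounds <- unique(agg$compound)
  keys <- unique(agg$key)

  fits <- list(); fit_rows <- list(); endpoints <- list()
  for (cp in compounds) {
    for (k in keys) {
      sub <- agg[agg$compound == cp & agg$key == k, ]
      fit <- fit_4pl(sub$concentration_mg_L, sub$peli,
                     c_range = config$c_range)
      fits[[paste(cp, k, sep = "|")]] <- fit
      fit_rows[[paste(cp, k, sep = "|")]] <- tibble::tibble(
        compound = cp, level = ifelse(k == "total", "total", "category"),
        key = k, A = fit$A, B = fit$B, C = fit$C, D = fit$D,
        sse = fit$sse, status = fit$status)
      ep <- tryCatch(
        peli15(fit, range = config$c_range, threshold = config$threshold),
        pelitox_invalid_fit = function(e) {
          # fitted baseline above the threshold: the response exceeds the
          # threshold throughout the studied range, i.e. a below-range endpoint
          structure(list(value = config$c_range[1], censor = "below_range",
                         range = config$c_range,
                         threshold = config$threshold),
                    class = "peli15_endpoint")
        })
      endpoints[[paste(cp, k, sep = "|")]] <- ep
    }
  }

  ref_fits <- NULL
  if (!is.null(references)) {
    ref_fits <- lapply(split(references, references$compound), function(sub) {
      fit <- fit_4pl(sub$concentration_mg_L, sub$peli,
                     c_range = range(sub$concentration_mg_L))
      fit$category <- sub$category[1]
      fit
    })
  }

  summary_rows <- lapply(compounds, function(cp) {
    row <- tibble::tibble(compound = cp)
    for (k in c("chemical", "general", "DNA", "oxidative", "protein", "total")) {
      ep <- endpoints[[paste(cp, k, sep = "|")]]
      row[[paste0("peli15_", k)]] <- if (is.null(ep)) NA_character_ else format(ep)
    }
    total_ep <- endpoints[[paste(cp, "total", sep = "|")]]
    geno <- oxi <- NULL
    if (!is.null(ref_fits)) {
      mmc <- Filter(function(f) identical(f$category, "DNA"), ref_fits)
      h2o2 <- Filter(function(f) identical(f$category, "oxidative"), ref_fits)
      if (length(mmc) > 0) {
        geno <- compute_teq(fits[[paste(cp, "DNA", sep = "|")]], total_ep,
                            mmc[[1]], ref_range = config$c_range)
      }
      if (length(h2o2) > 0) {
        oxi <- compute_teq(fits[[paste(cp, "oxidative", sep = "|")]], total_ep,
                           h2o2[[1]], ref_range = config$c_range)
      }
    }
    row$geno_teq <- if (is.null(geno)) NA_character_ else format(geno)
    row$oxi_teq <- if (is.null(oxi)) NA_character_ else format(oxi)
    row
  })

  endpoint_rows <- purrr::imap(endpoints, function(ep, nm) {
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    tibble::tibble(compound = parts[1], key = parts[2],
                   value_mg_L = ifelse(is.na(ep$value), NA_real_, ep$value),
                   censor = ep$censor, rendered = format(ep))
  })

  list(fits = fits, fit_table = dplyr::bind_rows(fit_rows),
       ref_fits = ref_fits,
       endpoints = dplyr::bind_rows(endpoint_rows),
       endpoint_objects = endpoints,
       summary = dplyr::bind_rows(summary_rows))
}

# Phenotypic anchoring: ROS fold vs oxidative/total PELI, comet tail DNA vs
# DNA-category PELI, with H2O2 equivalents when a standard curve is given.
phenotype_stage <- function(peli_tab, config) {
  ros <- resolve_table(config$ros,
                       function(p) readr::read_csv(p, show_col_types = FALSE))
  comet <- resolve_table(config$comet,
                         function(p) readr::read_csv(p, show_col_types = FALSE))
  std <- resolve_table(config$h2o2_standard,
                       function(p) readr::read_csv(p, show_col_types = FALSE))
  if (is.null(ros) && is.null(comet)) return(NULL)
  out <- list()

  if (!is.null(ros)) {
    cat_tab <- peli_tab[peli_tab$level %in% c("category", "total"), ]
    get_peli <- function(key) {
      sub <- cat_tab[cat_tab$key == key,
                     c("compound", "concentration_mg_L", "peli")]
      names(sub)[3] <- paste0("peli_", key)
      sub
    }
    merged <- dplyr::inner_join(ros, get_peli("oxidative"),
                                by = c("compound", "concentration_mg_L"))
    merged <- dplyr::inner_join(merged, get_peli("total"),
                                by = c("compound", "concentration_mg_L"))
    if (!is.null(std)) {
      eq <- lapply(merged$fold_change, h2o2_equivalent, standard_curve = std)
      merged$h2o2_equiv_mg_L <- vapply(eq, `[[`, 0, "value")
      merged$h2o2_equiv_censor <- vapply(eq, `[[`, "", "censor")
    }
    out$ros <- merged
    out$correlations <- dplyr::bind_rows(
      c(endpoint_pair = "ros_vs_peli_oxidative",
        correlate(merged$fold_change, merged$peli_oxidative)),
      c(endpoint_pair = "ros_vs_peli_total",
        correlate(merged$fold_change, merged$peli_total))
    )
  }

  if (!is.null(comet)) {
    control <- comet$tail_pct[comet$compound == "control"]
    if (length(control) < 2) {
      abort("comet table must include a 'control' compound group")
    }
    treatments <- setdiff(unique(comet$compound), "control")
    comet_rows <- lapply(treatments, function(cp) {
      cells <- comet$tail_pct[comet$compound == cp]
      res <- comet_positivity(cells, control)
      tibble::tibble(compound = cp, mean_tail_pct = res$mean_treatment,
                     delta_tail_pct = res$mean_treatment - res$mean_control,
                     p_value = res$p_value, positive = res$positive)
    })
    comet_tab <- dplyr::bind_rows(comet_rows)
    top_c <- max(peli_tab$concentration_mg_L)
    geno <- peli_tab[peli_tab$level == "category" & peli_tab$key == "DNA" &
                       peli_tab$concentration_mg_L == top_c, ]
    merged <- dplyr::inner_join(
      comet_tab, geno[, c("compound", "peli")], by = "compound")
    names(merged)[names(merged) == "peli"] <- "peli_DNA"
    out$comet <- merged
    if (nrow(merged) >= 3) {
      out$correlations <- dplyr::bind_rows(
        out$correlations,
        c(endpoint_pair = "tail_dna_vs_peli_DNA",
          correlate(merged$delta_tail_pct, merged$peli_DNA))
      )
    }
  }
  out
}

write_pipeline_outputs <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(tab, name) {
    readr::write_csv(tab, file.path(out_dir, name), na = "")
  }
  w(results$profiles, "ln_i.csv")
  w(results$peli, "peli.csv")
  mat_tab <- tibble::as_tibble(results$profile_matrix, rownames = "orf")
  w(mat_tab, "profile_matrix.csv")
  w(results$fits, "fits_4pl.csv")
  w(results$endpoints, "endpoints.csv")
  w(results$summary, "summary_table.csv")
  w(results$gsea, "gsea.csv")
  if (nrow(results$ontology) > 0) w(results$ontology, "ontology.csv")
  pca_tab <- pca_tables(results$pca)
  w(pca_tab$scores, "pca_scores.csv")
  w(pca_tab$variance, "pca_variance.csv")
  dendrogram_newick(results$clustering$conditions,
                    file.path(out_dir, "dendrogram_conditions.nwk"))
  dendrogram_newick(results$clustering$biomarkers,
                    file.path(out_dir, "dendrogram_biomarkers.nwk"))
  if (!is.null(results$phenotype)) {
    if (!is.null(results$phenotype$ros)) w(results$phenotype$ros, "ros_endpoints.csv")
    if (!is.null(results$phenotype$comet)) w(results$phenotype$comet, "comet_endpoints.csv")
    if (!is.null(results$phenotype$correlations))
      w(results$phenotype$correlations, "correlations.csv")
  }
  jsonlite::write_json(results$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
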