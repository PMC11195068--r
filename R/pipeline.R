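#' Run the full dyad-synchrony analysis
#'
#' Orchestrates the pipeline on an annotation table plus subject metadata:
#' ingest and validation, per-group synchrony with the virtual-dyad
#' correction, four-state decomposition with follow/retroact counts, and
#' group-level statistics. Results are returned and, when `out_dir` is
#' given, written as CSV tables, a markdown report and a checksum manifest.
#'
#' @param bout_source Bout table (path/connection/data frame) for
#'   [read_bout_table()].
#' @param metadata_source Subject metadata: columns `subject_id`, `dyad_id`,
#'   `sex` (`"M"`/`"F"`), `group`, `configuration` (`"PAIR"`/`"SINGLE"`).
#'   Path or data frame.
#' @param out_dir Output directory (created if needed); NULL to skip writing.
#' @param layout A [session_layout()].
#' @param end_convention Bout-end convention of the input table (see
#'   [read_bout_table()]).
#' @param method,n_surrogates Null model for [raw_synchrony()].
#' @param seed Pipeline seed; fanned out per dyad.
#' @param mode Motif-counting mode, `"strict"` or `"lenient"`.
#' @param split_fraction Fraction for [split_top_bottom()].
#' @return (Invisibly when writing) a list with `synchrony` (per-dyad table
#'   incl. behavior counts), `virtual` (virtual-dyad synchrony), `groups`
#'   (per-group summary), `correlations` (synchrony-behavior correlations
#'   per group), and `transitions` (flattened 16-cell counts per dyad).
#' @export
run_analysis <- function(bout_source, metadata_source, out_dir = NULL,
                         layout = session_layout(),
                         end_convention = "inclusive",
                         method = c("circular_shift", "binomial"),
                         n_surrogates = 1000L, seed = 17L,
                         mode = c("strict", "lenient"),
                         split_fraction = 0.40) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  meta <- if (is.data.frame(metadata_source)) metadata_source else {
    utils::read.csv(metadata_source, colClasses = "character")
  }
  need <- c("subject_id", "dyad_id", "sex", "group")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  if (!"configuration" %in% names(meta)) meta$configuration <- "PAIR"
  ethograms <- read_bout_table(bout_source, layout, end_convention)
  unknown <- setdiff(names(ethograms), meta$subject_id)
  if (length(unknown)) {
    stop("bout table contains subjects missing from metadata: ",
         paste(unknown, collapse = ", "))
  }
  # subjects with no recorded bouts still need (empty) ethograms
  for (sid in setdiff(meta$subject_id, names(ethograms))) {
    ethograms[[sid]] <- ethogram(sid, NULL, layout)
  }

  pair_meta <- meta[meta$configuration == "PAIR", , drop = FALSE]
  dyads_by_group <- build_dyads(pair_meta, ethograms)

  syn_rows <- list(); virt_rows <- list(); grp_rows <- list(); cor_rows <- list()
  beh_rows <- list(); trans_rows <- list()
  for (g in names(dyads_by_group)) {
    real <- dyads_by_group[[g]]
    if (length(real) < 2L) {
      stop("group '", g, "' has fewer than 2 dyads; virtual-dyad null undefined")
    }
    gs <- group_synchrony(real, method = method, n_surrogates = n_surrogates,
                          seed = seed)
    syn <- gs$real
    syn$group <- g
    syn$is_virtual <- FALSE
    virt <- gs$virtual
    if (nrow(virt)) { virt$group <- g; virt$is_virtual <- TRUE }

    extras <- lapply(real, function(d) {
      ta <- bouts_to_trace(d$ethogram_a)
      tb <- bouts_to_trace(d$ethogram_b)
      ss <- dyad_state_sequence(ta, tb)
      bc <- behavior_counts(ss, d$dyad_id, mode)
      tc <- transition_counts(ss)
      flat <- as.integer(t(tc))
      names(flat) <- paste0("t_", rep(0:3, each = 4L), rep(0:3, 4L))
      list(
        counts = bc,
        trans = data.frame(dyad_id = d$dyad_id, t(flat)),
        levels = data.frame(dyad_id = d$dyad_id,
                            subject_a = d$ethogram_a$subject_id,
                            subject_b = d$ethogram_b$subject_id,
                            freeze_a = freezing_level(ta),
                            freeze_b = freezing_level(tb))
      )
    })
    bc <- do.call(rbind, lapply(extras, `[[`, "counts"))
    lv <- do.call(rbind, lapply(extras, `[[`, "levels"))
    syn <- merge(merge(syn, bc, by = "dyad_id"), lv, by = "dyad_id")

    ok <- !is.na(syn$corrected)
    grp_rows[[g]] <- data.frame(
      group = g, n_dyads = nrow(syn), n_virtual = nrow(virt),
      nonsocial_component = gs$nonsocial_component,
      mean_corrected = mean(syn$corrected[ok]),
      sem_corrected = stats::sd(syn$corrected[ok]) / sqrt(sum(ok)),
      mean_follow = mean(syn$follow_total), mean_r2f = mean(syn$r2f),
      mean_r2m = mean(syn$r2m)
    )
    if (sum(ok) >= 3L) {
      cor_rows[[g]] <- do.call(rbind, lapply(
        c("follow_total", "r2f", "r2m"),
        function(b) {
          res <- try(synchrony_behavior_correlation(syn[ok, ], b), silent = TRUE)
          if (inherits(res, "try-error")) return(NULL)
          cbind(group = g, res)
        }
      ))
    }
    syn_rows[[g]] <- syn
    virt_rows[[g]] <- virt
    beh_rows[[g]] <- bc
    trans_rows[[g]] <- do.call(rbind, lapply(extras, `[[`, "trans"))
  }

  bind <- function(rows) if (length(rows)) do.call(rbind, unname(rows)) else NULL
  result <- list(
    synchrony = bind(syn_rows),
    virtual = bind(virt_rows),
    groups = bind(grp_rows),
    correlations = bind(cor_rows),
    transitions = bind(trans_rows),
    seed = seed, method = method, n_surrogates = n_surrogates
  )
  if (!is.null(out_dir)) {
    write_analysis_bundle(result, out_dir, split_fraction)
    return(invisible(result))
  }
  result
}

# Group PAIR metadata rows into dyad objects, male member first for MF dyads.
build_dyads <- function(meta, ethograms) {
  out <- list()
  for (g in unique(meta$group)) {
    mg <- meta[meta$group == g, , drop = FALSE]
    dyads <- lapply(unique(mg$dyad_id), function(did) {
      rows <- mg[mg$dyad_id == did, , drop = FALSE]
      if (nrow(rows) != 2L) {
        stop("dyad '", did, "' has ", nrow(rows), " subjects in metadata (need 2)")
      }
      sexes <- toupper(rows$sex)
      comp <- paste(sort(sexes, decreasing = TRUE), collapse = "")  # M before F
      comp <- switch(comp, MM = "MM", FF = "FF", MF = "MF",
                     stop("dyad '", did, "' has unparseable sexes: ",
                          paste(rows$sex, collapse = ",")))
      if (comp == "MF" && sexes[1L] != "M") rows <- rows[2:1, , drop = FALSE]
      dyad(did, ethograms[[rows$subject_id[1L]]], ethograms[[rows$subject_id[2L]]],
           sex_composition = comp, group = g)
    })
    out[[g]] <- dyads
  }
  out
}

write_analysis_bundle <- function(result, out_dir, split_fraction = 0.40) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    synchrony = file.path(out_dir, "synchrony.csv"),
    virtual = file.path(out_dir, "virtual_synchrony.csv"),
    behavior = file.path(out_dir, "behavior_counts.csv"),
    transitions = file.path(out_dir, "transition_counts.csv"),
    groups = file.path(out_dir, "group_summary.csv"),
    report = file.path(out_dir, "report.md")
  )
  syn <- result$synchrony
  utils::write.csv(
    syn[, c("dyad_id", "group", "is_virtual", "p_a", "p_b", "observed",
            "chance", "null_sd", "raw", "corrected")],
    paths["synchrony"], row.names = FALSE)
  utils::write.csv(result$virtual, paths["virtual"], row.names = FALSE)
  utils::write.csv(
    syn[, c("dyad_id", "f2f", "f2m", "follow_total", "r2f", "r2m")],
    paths["behavior"], row.names = FALSE)
  utils::write.csv(result$transitions, paths["transitions"], row.names = FALSE)
  utils::write.csv(result$groups, paths["groups"], row.names = FALSE)

  lines <- c("# Dyad synchrony report", "",
             sprintf("Seed %d | null: %s (%d surrogates)", result$seed,
                     result$method, result$n_surrogates), "",
             "## Group summary", "")
  for (i in seq_len(nrow(result$groups))) {
    gr <- result$groups[i, ]
    lines <- c(lines, sprintf(
      "- **%s**: n=%d dyads (%d virtual), non-social component %.3f, corrected synchrony %.2f +/- %.2f (mean +/- SEM)",
      gr$group, gr$n_dyads, gr$n_virtual, gr$nonsocial_component,
      gr$mean_corrected, gr$sem_corrected))
  }
  if (!is.null(result$correlations) && nrow(result$correlations)) {
    lines <- c(lines, "", "## Synchrony-behavior correlations (Pearson)", "")
    cr <- result$correlations
    for (i in seq_len(nrow(cr))) {
      lines <- c(lines, sprintf("- %s / %s: r = %.3f, p = %.4f (n = %d)",
                                cr$group[i], cr$behavior[i], cr$r[i], cr$p[i], cr$n[i]))
    }
  }
  lines <- c(lines, "", "## Top/bottom synchrony splits", "")
  for (g in unique(syn$group)) {
    sg <- syn[syn$group == g & !is.na(syn$corrected), ]
    if (nrow(sg) >= 5L) {
      sp <- split_top_bottom(sg, split_fraction)
      lines <- c(lines, sprintf(
        "- %s: top %d mean follow %.1f vs bottom %.1f; r2f %.1f vs %.1f; r2m %.1f vs %.1f",
        g, sp$k, mean(sp$top$follow_total), mean(sp$bottom$follow_total),
        mean(sp$top$r2f), mean(sp$bottom$r2f),
        mean(sp$top$r2m), mean(sp$bottom$r2m)))
    }
  }
  writeLines(lines, paths["report"])

  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  info <- data.frame(
    key = c("seed", "null_method", "n_surrogates", "package_version", "r_version"),
    value = c(result$seed, result$method, result$n_surrogates,
              as.character(utils::packageVersion("fearsync")),
              paste(R.version$major, R.version$minor, sep = "."))
  )
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(info, file.path(out_dir, "run_info.csv"), row.names = FALSE)
  invisible(paths)
}

#' Read a pipeline configuration file
#'
#' Parses a YAML configuration with optional `layout` and `synchrony`
#' blocks, e.g.:
#'
#' ```yaml
#' layout: {fps: 4, pre_cs_s: 60, cs_s: 120}
#' synchrony: {null: circular_shift, n_surrogates: 1000, seed: 17}
#' ```
#'
#' @param path Path to a YAML file.
#' @return A list with `layout` (a [session_layout()]) and `synchrony`
#'   (method, n_surrogates, seed), defaults filled in.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read configuration files")
  }
  raw <- yaml::read_yaml(path)
  lay <- raw$layout
  layout <- session_layout(
    fps = if (is.null(lay$fps)) 4L else lay$fps,
    pre_cs_s = if (is.null(lay$pre_cs_s)) 60 else lay$pre_cs_s,
    cs_s = if (is.null(lay$cs_s)) 120 else lay$cs_s
  )
  syn <- raw$synchrony
  # the null-model key may be spelled `method`, `"null"`, or a bare `null`
  # (which YAML parses as an empty-named entry)
  method <- syn$method
  if (is.null(method)) method <- syn[["null"]]
  if (is.null(method) && !is.null(names(syn)) && any(names(syn) == "")) {
    method <- syn[[which(names(syn) == "")[1L]]]
  }
  list(
    layout = layout,
    synchrony = list(
      method = if (is.null(method)) "circular_shift" else method,
      n_surrogates = if (is.null(syn$n_surrogates)) 1000L else as.integer(syn$n_surrogates),
      seed = if (is.null(syn$seed)) 17L else as.integer(syn$seed)
    )
  )
}

#' End-to-end demonstration on simulated cohorts
#'
#' Simulates an uncoupled control-like cohort and a follow-coupled cohort
#' with across-dyad heterogeneity, writes their bout/metadata tables, and
#' runs the full analysis. Serves as a smoke test of the whole pipeline and
#' as a template for real annotation data.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory; NULL returns results without writing.
#' @param n_dyads Dyads per cohort.
#' @param n_surrogates Surrogates for the circular-shift null (lowered from
#'   the analysis default to keep the demo quick).
#' @return The [run_analysis()] result list, plus `bout_table` and
#'   `metadata` elements with the simulated inputs.
#' @export
run_demo <- function(seed = 17L, out_dir = NULL, n_dyads = 12L,
                     n_surrogates = 200L) {
  cfg <- sim_config()
  uncoupled <- simulate_cohort(cfg, n_dyads, seed = seed, group = "uncoupled",
                               id_prefix = "u")
  coupled <- simulate_cohort(cfg, n_dyads, seed = seed, group = "follow_coupled",
                             id_prefix = "c", gamma_follow_range = c(0.5, 4))
  dyads <- c(uncoupled$dyads, coupled$dyads)
  eths <- do.call(c, lapply(dyads, function(d) list(d$ethogram_a, d$ethogram_b)))
  bout_tab <- write_bout_table(eths)
  metadata <- do.call(rbind, lapply(dyads, function(d) {
    data.frame(subject_id = c(d$ethogram_a$subject_id, d$ethogram_b$subject_id),
               dyad_id = d$dyad_id, sex = c(d$sex_a, d$sex_b),
               group = d$group, configuration = d$configuration)
  }))
  res <- run_analysis(bout_tab, metadata, out_dir = out_dir,
                      n_surrogates = n_surrogates, seed = seed)
  res$bout_table <- bout_tab
  res$metadata <- metadata
  if (!is.null(out_dir)) {
    utils::write.csv(bout_tab, file.path(out_dir, "simulated_bouts.csv"),
                     row.names = FALSE)
    utils::write.csv(metadata, file.path(out_dir, "simulated_metadata.csv"),
                     row.names = FALSE)
  }
  invisible(res)
}
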