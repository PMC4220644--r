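feature_names <- c("area_fraction", "morisita_index", "entropy", "asm",
                   "variance", "correlation", "fractal_D", "lacunarity")

#' Extract every morphometric feature from one histology image
#'
#' Runs the full single-image pipeline: red-channel extraction,
#' thresholding, geometric filtering, then (i) area fraction and Morisita's
#' index on the binary connective-tissue pattern, (ii) GLCM texture
#' features on the gray image, and (iii) skeletonization followed by
#' box-counting fractal dimension and lacunarity. All stages are controlled
#' by `config`; with a fixed configuration the record is fully
#' deterministic (grid origins are seeded).
#'
#' A segmentation that leaves fewer than 2 foreground pixels yields a
#' flagged record (`status` column) with `NA` features rather than silent
#' zeros; a constant-colour image makes Otsu thresholding fail with an
#' error.
#'
#' @param image Path to an RGB TIFF/PNG, or an integer array
#'   `[height, width, 3]` with 8-bit values.
#' @param config Configuration list, see [default_config()].
#' @param image_id Identifier stored in the record; defaults to the file
#'   name (or `"image"` for in-memory arrays).
#' @return One-row data.frame: `image_id`, the eight features, `status`
#'   (`"ok"` or `"empty_mask"`), `config_hash`.
#' @export
analyze_image <- function(image, config = default_config(), image_id = NULL) {
  if (is.character(image)) {
    if (is.null(image_id)) image_id <- basename(image)
    image <- read_image_rgb(image)
  }
  if (is.null(image_id)) image_id <- "image"
  assert_rgb_image(image, "image")

  gray <- extract_red_channel(image)
  seg <- config$segmentation
  mask <- geometric_filter(threshold_image(gray, seg), seg)

  rec <- data.frame(image_id = image_id, stringsAsFactors = FALSE)
  for (f in feature_names) rec[[f]] <- NA_real_
  rec$status <- "ok"
  rec$config_hash <- config_hash(config)

  gl <- config$glcm
  if (isTRUE(gl$use_mask) && sum(mask) < 2) {
    rec$status <- "empty_mask"
    return(rec)
  }
  tf <- texture_features(
    compute_glcm(gray, distance = gl$distance, angle = gl$angle,
                 levels = gl$levels, symmetric = gl$symmetric,
                 mask = if (isTRUE(gl$use_mask)) mask else NULL),
    log_base = gl$log_base)
  rec$entropy <- tf$entropy
  rec$asm <- tf$asm
  rec$variance <- tf$variance
  rec$correlation <- tf$correlation

  if (sum(mask) < 2) {
    rec$status <- "empty_mask"
    return(rec)
  }
  rec$area_fraction <- area_fraction(mask)
  mo <- config$morisita
  rec$morisita_index <- morisita_index(mask, mo$grid_rows, mo$grid_cols)$index_value

  fr <- config$fractal
  target <- if (isTRUE(fr$use_skeleton)) skeletonize(mask) else mask
  if (sum(target) < 2) {
    rec$status <- "empty_mask"
    return(rec)
  }
  rec$fractal_D <- fractal_dimension(target, sizes = fr$sizes,
                                     n_origins = fr$n_origins,
                                     seed = fr$seed)$mean_D
  rec$lacunarity <- lacunarity(target, sizes = fr$sizes,
                               n_origins = fr$n_origins, seed = fr$seed,
                               mode = fr$lacunarity_mode)
  rec
}

#' Run a full group-comparison study
#'
#' Analyzes every image in the manifest, aggregates features to subject
#' level (mean over a subject's images, so each subject is one sampling
#' unit for inference), and for every feature runs a one-way ANOVA, Dunnett
#' comparisons against the control group, a Bonferroni-adjusted pooled t
#' test for the designated comparison pair, and a ROC analysis of that pair
#' with accuracy banding.
#'
#' @param manifest Data frame (or CSV path) with columns `image` (file
#'   paths, or a list column of in-memory RGB arrays), `subject_id` and
#'   `group`; optional `image_id`. Group order of first appearance is kept.
#' @param config Configuration list, see [default_config()].
#' @param control Control group label; default the first group.
#' @param comparison Character vector of 2 group labels for the pairwise
#'   and ROC analyses; default the last two non-control groups (or the only
#'   two groups). The second label is the ROC positive class.
#' @param skip_missing Drop manifest rows whose image file is missing
#'   instead of aborting.
#' @param out_dir Optional directory: writes `features.csv`,
#'   `subjects.csv`, `summary.csv`, `anova.csv`, `dunnett.csv`,
#'   `pairwise.csv`, `roc.csv` and `run_metadata.yaml`.
#' @return Object of class `study_result` with elements `features`,
#'   `subjects`, `anova`, `dunnett`, `pairwise`, `roc`, `summary`,
#'   `groups`, `control`, `comparison`, `metadata`.
#' @export
run_study <- function(manifest, config = default_config(), control = NULL,
                      comparison = NULL, skip_missing = FALSE, out_dir = NULL) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  need <- c("image", "subject_id", "group")
  if (!all(need %in% names(manifest)))
    stop("manifest needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  groups <- unique(as.character(manifest$group))
  if (length(groups) < 2)
    stop("a study needs >= 2 groups", call. = FALSE)
  if (is.character(manifest$image)) {
    missing <- !file.exists(manifest$image)
    if (any(missing)) {
      if (!skip_missing)
        stop("missing image files:\n  ",
             paste(manifest$image[missing], collapse = "\n  "), call. = FALSE)
      manifest <- manifest[!missing, , drop = FALSE]
    }
  }

  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- if ("image_id" %in% names(manifest)) manifest$image_id[i] else NULL
    r <- analyze_image(manifest$image[[i]], config, image_id = id)
    r$subject_id <- as.character(manifest$subject_id[i])
    r$group <- as.character(manifest$group[i])
    r
  })
  features <- do.call(rbind, recs)

  ok <- features[features$status == "ok", , drop = FALSE]
  if (!nrow(ok)) stop("no image produced a usable feature record", call. = FALSE)
  subjects <- stats::aggregate(ok[feature_names],
                               by = list(subject_id = ok$subject_id,
                                         group = ok$group), FUN = mean)
  subjects <- subjects[order(match(subjects$group, groups),
                             subjects$subject_id), , drop = FALSE]
  rownames(subjects) <- NULL

  if (is.null(control)) control <- groups[1]
  if (!control %in% groups) stop("unknown control group: ", control, call. = FALSE)
  if (is.null(comparison)) {
    nonc <- setdiff(groups, control)
    comparison <- if (length(nonc) >= 2) utils::tail(nonc, 2) else groups[1:2]
  }
  if (length(comparison) != 2 || !all(comparison %in% groups))
    stop("`comparison` must name two groups present in the manifest", call. = FALSE)

  split_feature <- function(f) {
    lapply(groups, function(g) subjects[[f]][subjects$group == g])
  }
  st <- config$stats
  anova_tab <- NULL; dunnett_tab <- NULL; pair_tab <- NULL; roc_tab <- NULL
  ctrl_i <- match(control, groups)
  cmp_i <- match(comparison, groups)
  for (f in feature_names) {
    vals <- split_feature(f)
    av <- one_way_anova(vals)
    anova_tab <- rbind(anova_tab,
                       data.frame(feature = f, F = av$statistic, p = av$p.value))
    dn <- dunnett_vs_control(vals, control = ctrl_i, n_mc = st$n_mc,
                             seed = st$seed)
    dn <- data.frame(feature = f, group = groups[dn$group],
                     estimate = dn$estimate, t = dn$t, p_raw = dn$p_raw,
                     p_adj = dn$p_adj)
    dunnett_tab <- rbind(dunnett_tab, dn)
    bp <- bonferroni_pairs(vals, list(cmp_i))
    pair_tab <- rbind(pair_tab,
                      data.frame(feature = f, group_i = comparison[1],
                                 group_j = comparison[2], estimate = bp$estimate,
                                 p_raw = bp$p_raw, p_adj = bp$p_adj))
    dir <- st$roc_direction[[f]]
    if (is.null(dir)) dir <- "greater_is_positive"
    rc <- roc_curve(vals[[cmp_i[2]]], vals[[cmp_i[1]]], direction = dir)
    roc_tab <- rbind(roc_tab,
                     data.frame(feature = f, auc = rc$auc,
                                band = as.character(rc$band),
                                direction = dir))
  }

  flag <- function(p) ifelse(p < 0.01, "**", ifelse(p < st$alpha, "*", ""))
  summary_tab <- NULL
  for (f in feature_names) {
    row <- data.frame(feature = f)
    for (g in groups) {
      v <- subjects[[f]][subjects$group == g]
      sig <- if (g == control) "" else
        flag(dunnett_tab$p_adj[dunnett_tab$feature == f & dunnett_tab$group == g])
      row[[paste0(g, "_mean")]] <- mean(v)
      row[[paste0(g, "_sem")]] <- sd(v) / sqrt(length(v))
      row[[paste0(g, "_vs_control")]] <- sig
    }
    row$pair_sig <- flag(pair_tab$p_adj[pair_tab$feature == f])
    summary_tab <- rbind(summary_tab, row)
  }

  res <- structure(
    list(features = features, subjects = subjects, anova = anova_tab,
         dunnett = dunnett_tab, pairwise = pair_tab, roc = roc_tab,
         summary = summary_tab, groups = groups, control = control,
         comparison = comparison,
         metadata = list(config = config, config_hash = config_hash(config),
                         n_images = nrow(features),
                         n_flagged = sum(features$status != "ok"),
                         version = as.character(packageVersion("morphotex")))),
    class = "study_result")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wr <- function(x, name) write.csv(x, file.path(out_dir, name), row.names = FALSE)
    fx <- features; fx$image <- NULL
    wr(fx, "features.csv"); wr(subjects, "subjects.csv")
    wr(summary_tab, "summary.csv"); wr(anova_tab, "anova.csv")
    wr(dunnett_tab, "dunnett.csv"); wr(pair_tab, "pairwise.csv")
    wr(roc_tab, "roc.csv")
    yaml::write_yaml(res$metadata, file.path(out_dir, "run_metadata.yaml"))
  }
  res
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("Morphometric study: %d images, groups %s (control: %s)\n",
              x$metadata$n_images, paste(x$groups, collapse = ", "), x$control))
  if (x$metadata$n_flagged > 0)
    cat(sprintf("  %d image(s) flagged (empty segmentation)\n", x$metadata$n_flagged))
  cat("\nGroup summary (mean +/- s.e.m., flags vs. control and for the pair):\n")
  print(x$summary, digits = 4)
  cat(sprintf("\nROC discrimination, %s vs %s (positive class: %s):\n",
              x$comparison[1], x$comparison[2], x$comparison[2]))
  print(x$roc, digits = 4)
  invisible(x)
}
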