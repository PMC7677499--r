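#' Full single-structure analysis
#'
#' Runs the rotation-averaged cavity search, the surface/closure analysis and
#' the shell descriptors, and assembles one survey record.
#'
#' @param structure An `sb_structure`.
#' @param params An `sb_params`.
#' @param chains Chain-selection annotation carried into the record (the
#'   structure is assumed already subset).
#' @return Object of class `sb_record`: the underlying `result`, `metrics`,
#'   `shell`, `descriptors`, and a one-row data frame `row`.
#' @export
analyze_structure <- function(structure, params = probe_params(), chains = NULL) {
  result <- run_spaceball(structure, params)
  metrics <- surface_metrics(result, params)
  shell <- assign_shell(metrics$surface, structure)
  desc <- shell_descriptors(shell)
  s <- result$summary
  ref <- result$rotations[[result$reference_rotation]]
  row <- data.frame(
    id = structure$id,
    chains = if (is.null(chains)) "" else paste(chains, collapse = ","),
    V_T = s$V_T_mean,
    V_C = s$V_C_mean,
    V_C_over_V_T = if (s$V_T_mean > 0) s$V_C_mean / s$V_T_mean else NA_real_,
    n_chambers = ref$n_chambers,
    S_C = metrics$S_C,
    S_CP = metrics$S_CP,
    s = metrics$s,
    label = if (is.null(metrics$label_class)) NA_character_ else metrics$label_class,
    N_CP = desc$N_CP,
    H = desc$H,
    h_norm = desc$h_norm,
    H_per_residue = desc$H_per_residue,
    R_g = desc$R_g,
    R1 = desc$R1, R2 = desc$R2, R3 = desc$R3,
    w = desc$w,
    V_C_sd = if (is.na(s$V_C_sd)) 0 else s$V_C_sd,
    a = params$a, r_w = params$r_w,
    n_rotations = params$n_rotations, seed = params$seed,
    radii_hash = attr(structure, "radii_hash") %||% .sb_stable_hash(paste(
      names(default_vdw_radii()), default_vdw_radii(), collapse = ";")),
    status = "ok", reason = "",
    stringsAsFactors = FALSE
  )
  base::structure(list(result = result, metrics = metrics, shell = shell,
                       descriptors = desc, row = row),
                  class = "sb_record")
}

#' @export
print.sb_record <- function(x, ...) {
  print(x$result)
  print(x$metrics)
  print(x$descriptors)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic small-integer hash of a string (order-independent batch seeds)
.sb_stable_hash <- function(x) {
  h <- 0
  for (c in utf8ToInt(as.character(x))) h <- (h * 31 + c) %% 1048573
  as.integer(h)
}

.sb_failure_row <- function(id, chains, reason, params) {
  row <- data.frame(
    id = id, chains = if (is.null(chains) || is.na(chains)) "" else chains,
    V_T = NA_real_, V_C = NA_real_, V_C_over_V_T = NA_real_,
    n_chambers = NA_integer_, S_C = NA_real_, S_CP = NA_real_, s = NA_real_,
    label = NA_character_, N_CP = NA_integer_, H = NA_real_,
    h_norm = NA_real_, H_per_residue = NA_real_, R_g = NA_real_,
    R1 = NA_real_, R2 = NA_real_, R3 = NA_real_, w = NA_real_,
    V_C_sd = NA_real_, a = params$a, r_w = params$r_w,
    n_rotations = params$n_rotations, seed = params$seed,
    radii_hash = NA_integer_, status = "error", reason = reason,
    stringsAsFactors = FALSE
  )
  row
}

#' Batch survey over a manifest of structures
#'
#' Analyzes every manifest entry with a per-entry seed derived from the base
#' seed and a stable hash of the entry id, so results are order-independent
#' and individually reproducible. Failures are recorded as error rows and
#' never abort the batch.
#'
#' @param manifest Data frame with columns `path` and optional `chains`
#'   (comma-separated), or the path to a TSV of `path<TAB>chains`.
#' @param params An `sb_params`; the per-entry seed replaces `params$seed`.
#' @return Object of class `sb_survey`: `records` (one row per entry) and
#'   `params`.
#' @export
run_survey <- function(manifest, params = probe_params()) {
  if (is.character(manifest)) {
    manifest <- utils::read.table(manifest, sep = "\t", header = FALSE,
                                  col.names = c("path", "chains")[1:2],
                                  fill = TRUE, stringsAsFactors = FALSE,
                                  quote = "", comment.char = "#")
  }
  if (!is.data.frame(manifest) || nrow(manifest) == 0) stop("empty manifest")
  if (is.null(manifest$chains)) manifest$chains <- ""
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    path <- manifest$path[i]
    chains_str <- manifest$chains[i]
    chains <- if (is.na(chains_str) || !nzchar(chains_str)) NULL else
      strsplit(chains_str, ",")[[1]]
    entry_id <- paste0(basename(path), "|", chains_str)
    p_i <- params
    p_i$seed <- as.integer((as.numeric(params$seed) + .sb_stable_hash(entry_id)) %% 2147483647)
    rows[[i]] <- tryCatch({
      st <- read_structure(path, chains = chains)
      st <- assign_radii(st)
      rec <- analyze_structure(st, p_i, chains = chains)
      rec$row
    }, error = function(e) .sb_failure_row(basename(path), chains_str,
                                           conditionMessage(e), p_i))
  }
  base::structure(list(records = do.call(rbind, rows), params = params),
                  class = "sb_survey")
}

#' Summarize a survey
#'
#' Gaussian summary of the closure fractions (mean, sample standard deviation,
#' pocket threshold `mean - 3 sd`), pocket/cavity counts, a hydrophobicity
#' histogram and the extreme structures.
#'
#' @param records An `sb_survey` or its `records` data frame.
#' @param h_breaks Histogram breaks for H (passed to [hist()]).
#' @param top_k How many extreme structures to list.
#' @return Object of class `sb_survey_summary`.
#' @export
summarize_survey <- function(records, h_breaks = "Sturges", top_k = 5L) {
  if (inherits(records, "sb_survey")) records <- records$records
  ok <- records[records$status == "ok", , drop = FALSE]
  s_def <- ok$s[!is.na(ok$s)]
  s_bar <- if (length(s_def) >= 1) mean(s_def) else NA_real_
  s_sd <- if (length(s_def) >= 2) stats::sd(s_def) else NA_real_
  threshold <- if (length(s_def) >= 2) s_bar - 3 * s_sd else NA_real_
  h_def <- ok$H[!is.na(ok$H)]
  h_hist <- if (length(h_def) > 0) {
    hh <- graphics::hist(h_def, breaks = h_breaks, plot = FALSE)
    list(breaks = hh$breaks, counts = hh$counts)
  } else list(breaks = numeric(0), counts = integer(0))
  lab <- classify_pocket(ok$s, if (is.na(threshold)) 0.21 else threshold)
  top <- function(df, col, decreasing) {
    df <- df[!is.na(df[[col]]), , drop = FALSE]
    df[order(df[[col]], decreasing = decreasing), c("id", col)][
      seq_len(min(top_k, nrow(df))), , drop = FALSE]
  }
  base::structure(list(
    n = nrow(records), n_ok = nrow(ok),
    s_bar = s_bar, s_sd = s_sd, pocket_threshold = threshold,
    n_pockets = sum(lab == "pocket", na.rm = TRUE),
    n_cavities = sum(lab == "cavity", na.rm = TRUE),
    H_hist = h_hist,
    top_hydrophobic = top(ok, "H", TRUE),
    top_hydrophilic = top(ok, "H", FALSE),
    top_volume = top(ok, "V_C", TRUE),
    top_closure = top(ok, "s", TRUE)
  ), class = "sb_survey_summary")
}

#' @export
print.sb_survey_summary <- function(x, ...) {
  cat(sprintf("survey summary: %d/%d structures analyzed\n", x$n_ok, x$n))
  if (!is.na(x$s_bar)) {
    cat(sprintf("  s = %.2f +/- %.2f, pocket threshold (mean - 3 sd) = %.2f\n",
                x$s_bar, if (is.na(x$s_sd)) 0 else x$s_sd,
                if (is.na(x$pocket_threshold)) NA else x$pocket_threshold))
    cat(sprintf("  %d pocket(s), %d cavity(ies)\n", x$n_pockets, x$n_cavities))
  }
  invisible(x)
}

# Table-style fixed-precision formatting: V nm^3 and S nm^2 2 dp, s/w 2 dp,
# R in A 2 dp, H 1 dp.
.sb_fmt <- function(x, digits) ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), x))

#' Write survey records as TSV
#'
#' Deterministic fixed-precision text: volumes (nm^3), surfaces (nm^2), s, w
#' and radii (A) at 2 decimals, H at 1 decimal.
#'
#' @param survey An `sb_survey` or records data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_survey_tsv <- function(survey, path) {
  rec <- if (inherits(survey, "sb_survey")) survey$records else survey
  out <- data.frame(
    id = rec$id, chains = rec$chains,
    V_T = .sb_fmt(rec$V_T, 2), V_C = .sb_fmt(rec$V_C, 2),
    V_C_over_V_T = .sb_fmt(rec$V_C_over_V_T, 3),
    n_chambers = rec$n_chambers,
    S_C = .sb_fmt(rec$S_C, 2), S_CP = .sb_fmt(rec$S_CP, 2),
    s = .sb_fmt(rec$s, 2), label = rec$label,
    N_CP = rec$N_CP, H = .sb_fmt(rec$H, 1),
    h_norm = .sb_fmt(rec$h_norm, 1), H_per_residue = .sb_fmt(rec$H_per_residue, 2),
    R_g = .sb_fmt(rec$R_g, 2),
    R1 = .sb_fmt(rec$R1, 2), R2 = .sb_fmt(rec$R2, 2), R3 = .sb_fmt(rec$R3, 2),
    w = .sb_fmt(rec$w, 2), V_C_sd = .sb_fmt(rec$V_C_sd, 2),
    a = rec$a, r_w = rec$r_w, n_rotations = rec$n_rotations, seed = rec$seed,
    radii_hash = rec$radii_hash, status = rec$status, reason = rec$reason,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read survey records back from TSV
#'
#' @param path TSV path written by [write_survey_tsv()].
#' @return Records data frame (numeric columns re-parsed).
#' @export
read_survey_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    quote = "", na.strings = "NA")
}
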