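# Model-quality metrics and summary statistics over benchmark result tables.

#' Evaluate a structural model against a native structure
#'
#' @param model_structure,native_structure Backbone structures of equal
#'   length (vacant positions in either are excluded).
#' @return One-row tibble: `ca_rmsd` and `backbone_rmsd` (Angstrom, after
#'   Kabsch superposition), `gdt_1`, `gdt_2`, `gdt_4`, `gdt_8` and `gdt_ts`.
#' @export
evaluate_model <- function(model_structure, native_structure) {
  validate_backbone(model_structure); validate_backbone(native_structure)
  if (n_residues(model_structure) != n_residues(native_structure))
    stop("structures differ in length")
  mask_res <- !(model_structure$vacant | native_structure$vacant)
  mask_atoms <- rep(mask_res, each = 4)
  ca <- kabsch_superpose(ca_xyz(model_structure)[mask_res, , drop = FALSE],
                         ca_xyz(native_structure)[mask_res, , drop = FALSE])
  bb <- kabsch_superpose(backbone_xyz(model_structure)[mask_atoms, , drop = FALSE],
                         backbone_xyz(native_structure)[mask_atoms, , drop = FALSE])
  g <- vapply(c(1, 2, 4, 8), function(ct)
    gdt(model_structure, native_structure, ct), numeric(1))
  tibble::tibble(ca_rmsd = ca$rmsd_after, backbone_rmsd = bb$rmsd_after,
                 gdt_1 = g[1], gdt_2 = g[2], gdt_4 = g[3], gdt_8 = g[4],
                 gdt_ts = mean(g))
}

#' Count values strictly below a threshold
#' @param values Numeric vector (e.g. per-target CA RMSDs in Angstrom).
#' @param threshold Threshold (strict inequality).
#' @return Integer count.
#' @export
count_below_threshold <- function(values, threshold) {
  sum(values < threshold)
}

# Regularized incomplete beta function I_x(a, b) by the standard continued
# fraction (modified Lentz), self-contained.
inc_beta_reg <- function(x, a, b) {
  if (x <= 0) return(0)
  if (x >= 1) return(1)
  lbeta_ab <- lgamma(a) + lgamma(b) - lgamma(a + b)
  front <- exp(a * log(x) + b * log(1 - x) - lbeta_ab)
  # continued fraction converges fastest for x < (a + 1) / (a + b + 2)
  if (x < (a + 1) / (a + b + 2)) {
    front / a * betacf(x, a, b)
  } else {
    1 - front / b * betacf(1 - x, b, a)
  }
}

betacf <- function(x, a, b, max_iter = 300, eps = 3e-14) {
  tiny <- 1e-30
  qab <- a + b; qap <- a + 1; qam <- a - 1
  c_ <- 1; d <- 1 - qab * x / qap
  if (abs(d) < tiny) d <- tiny
  d <- 1 / d; h <- d
  for (m in seq_len(max_iter)) {
    m2 <- 2 * m
    aa <- m * (b - m) * x / ((qam + m2) * (a + m2))
    d <- 1 + aa * d; if (abs(d) < tiny) d <- tiny
    c_ <- 1 + aa / c_; if (abs(c_) < tiny) c_ <- tiny
    d <- 1 / d; h <- h * d * c_
    aa <- -(a + m) * (qab + m) * x / ((a + m2) * (qap + m2))
    d <- 1 + aa * d; if (abs(d) < tiny) d <- tiny
    c_ <- 1 + aa / c_; if (abs(c_) < tiny) c_ <- tiny
    d <- 1 / d; del <- d * c_; h <- h * del
    if (abs(del - 1) < eps) break
  }
  h
}

#' Paired two-tailed t-test
#'
#' Standard paired t on the differences (`df = n - 1`); the two-tailed
#' p-value is computed from the t distribution through a self-contained
#' regularized incomplete-beta evaluation.
#'
#' @param a,b Numeric vectors of equal length `n >= 2`.
#' @return A list with `t`, `df` and `p` (two-tailed).
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("a and b differ in length")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  d <- a - b
  s <- sd(d)
  if (s == 0) stop("zero-variance differences: paired t-test undefined")
  t_stat <- mean(d) / (s / sqrt(n))
  df <- n - 1
  p <- inc_beta_reg(df / (df + t_stat^2), df / 2, 0.5)
  list(t = t_stat, df = df, p = p)
}

#' Load a packaged benchmark results table
#'
#' Two benchmark tables ship with the package as plain TSV: a 14-target
#' single-template comparison of the autoencoder reconstruction against
#' MODELLER (GDT at the 2 Angstrom cutoff plus CA RMSD per method), and a
#' 21-target comparison against MODELLER and I-TASSER on targets with high
#' template sequence similarity (GDT-TS plus CA RMSD per method).
#'
#' @param which `"single_template_14"` or `"high_similarity_21"`.
#' @return A tibble with columns `target`, `length` and
#'   `<method>_gdt` / `<method>_crmsd` pairs.
#' @export
load_benchmark_table <- function(which = c("high_similarity_21",
                                           "single_template_14")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("benchmark_", which, ".tsv"),
                      package = "prsda", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
}

#' Summarize a benchmark results table
#'
#' Computes, per method column: the count of targets with CA RMSD strictly
#' below `threshold`, column means, and pairwise paired t-tests between every
#' pair of method columns on each metric.  A zero-variance pair is not
#' testable and is reported with a diagnostic instead of a p-value.
#'
#' @param table A tibble as returned by [load_benchmark_table()]: columns
#'   `target`, `length`, then `<method>_gdt`/`<method>_crmsd` (or `_gdt_ts`).
#' @param threshold CA RMSD threshold in Angstrom (default 1.0, strict).
#' @param file Optional path; if given the report is also written as
#'   tab-separated text.
#' @return List of tibbles: `counts`, `means`, `paired_tests`.
#' @export
results_table_report <- function(table, threshold = 1.0, file = NULL) {
  metric_cols <- setdiff(names(table), c("target", "length"))
  if (anyNA(table[metric_cols])) stop("ragged table: missing metric values")
  parts <- regmatches(metric_cols, regexpr("_(gdt_ts|gdt|crmsd)$", metric_cols))
  methods <- unique(sub("_(gdt_ts|gdt|crmsd)$", "", metric_cols))
  metrics <- unique(sub("^_", "", parts))

  counts <- do.call(rbind, lapply(methods, function(m) {
    col <- paste0(m, "_crmsd")
    if (!col %in% names(table)) return(NULL)
    tibble::tibble(method = m, metric = "crmsd", threshold = threshold,
                   count = count_below_threshold(table[[col]], threshold),
                   n = nrow(table))
  }))
  means <- do.call(rbind, lapply(metric_cols, function(cl)
    tibble::tibble(column = cl, mean = mean(table[[cl]]))))

  pairs <- utils::combn(methods, 2, simplify = FALSE)
  paired_tests <- do.call(rbind, unlist(lapply(metrics, function(met) {
    lapply(pairs, function(pr) {
      ca <- paste0(pr[1], "_", met); cb <- paste0(pr[2], "_", met)
      if (!all(c(ca, cb) %in% names(table))) return(NULL)
      res <- tryCatch(paired_ttest(table[[ca]], table[[cb]]),
                      error = function(e) conditionMessage(e))
      if (is.character(res))
        tibble::tibble(method_a = pr[1], method_b = pr[2], metric = met,
                       t = NA_real_, df = NA_integer_, p = NA_real_,
                       note = res)
      else
        tibble::tibble(method_a = pr[1], method_b = pr[2], metric = met,
                       t = res$t, df = res$df, p = res$p, note = "")
    })
  }), recursive = FALSE))

  report <- list(counts = counts, means = means, paired_tests = paired_tests)
  if (!is.null(file)) {
    con <- file(file, "w"); on.exit(close(con))
    for (nm in names(report)) {
      writeLines(paste0("# ", nm), con)
      utils::write.table(report[[nm]], con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      writeLines("", con)
    }
  }
  report
}
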