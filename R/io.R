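#' Read a numeric matrix from headerless TSV
#'
#' Strict reader for the package's matrix format: tab-separated numeric
#' values, no header, '.' decimal. Ragged rows, non-numeric cells and
#' NaN/Inf are rejected with the offending location.
#'
#' @param path File path.
#' @param expect_square If `TRUE`, require as many rows as columns.
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path, expect_square = FALSE) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_format(sprintf("empty matrix file: %s", path))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(cells)
  if (any(ncols != ncols[1])) {
    bad <- which(ncols != ncols[1])[1]
    stop_format(sprintf("row %d has %d columns, expected %d", bad, ncols[bad], ncols[1]))
  }
  m <- matrix(NA_real_, length(cells), ncols[1])
  for (i in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[i]]))
    if (anyNA(v) || any(!is.finite(v))) {
      j <- which(is.na(v) | !is.finite(v))[1]
      stop_format(sprintf("non-numeric or non-finite value at row %d col %d: '%s'",
                          i, j, cells[[i]][j]))
    }
    m[i, ] <- v
  }
  if (expect_square && nrow(m) != ncol(m)) {
    stop_format(sprintf("expected a square matrix, got %d x %d", nrow(m), ncol(m)))
  }
  m
}

#' Write a numeric matrix as headerless TSV
#'
#' @param m Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

subject_columns <- c("id", "sex", "age", "bmi", "whr",
                     "edeq_r", "edeq_e", "edeq_s", "edeq_w")

#' Read a subject table
#'
#' TSV with header columns `id`, `sex`, `age`, `bmi`, `whr`, `edeq_r`,
#' `edeq_e`, `edeq_s`, `edeq_w` (and optionally `group`). Sex tokens
#' `M`/`F`/`male`/`female` are normalised; when `group` is absent it is
#' derived from sex and WHR via [classify_whr()].
#'
#' @param path File path.
#' @return Tibble of subject records with a `group` column.
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(subject_columns, names(tab))
  if (length(missing) > 0L) {
    stop_format(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")))
  }
  num_cols <- setdiff(subject_columns, c("id", "sex"))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v)) {
      stop_format(sprintf("unparseable value in column `%s`, row %d: '%s'",
                          col, which(is.na(v))[1], tab[[col]][which(is.na(v))[1]]))
    }
    tab[[col]] <- v
  }
  tab$sex <- normalize_sex(tab$sex)
  if (any(tab$whr <= 0)) stop_format("`whr` must be positive")
  if (any(tab$age <= 0)) stop_format("`age` must be positive")
  edeq <- c("edeq_r", "edeq_e", "edeq_s", "edeq_w")
  if (any(unlist(tab[edeq]) < 0)) stop_format("EDE-Q scores must be nonnegative")
  if (!"group" %in% names(tab)) {
    tab$group <- classify_whr(tab$sex, tab$whr)
  }
  tab[c(subject_columns[1:5], "group", edeq)]
}

#' Write a subject table as TSV
#'
#' @param subjects Subject tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(subjects, path) {
  readr::write_tsv(subjects, path, progress = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every parameter of the full analysis into one validated object.
#' Paths are checked at run time by [run_pipeline()].
#'
#' @param ts_dir Directory with per-subject `ts_<id>.tsv` node-by-time
#'   matrices.
#' @param fiber_dir Directory with per-subject `fiber_<id>.tsv` matrices.
#' @param subjects Path to the subject table TSV.
#' @param out_dir Output directory (created if absent).
#' @param tr Sampling interval of the time series, seconds.
#' @param beta Soft-threshold exponent.
#' @param window A [window_config()]; `NULL` derives the window length from
#'   `tr` and `min_freq`.
#' @param min_freq Lowest frequency to capture when deriving the window.
#' @param lambda Graphical-lasso penalty (scalar) or candidate grid.
#' @param k Number of brain states; `NULL` selects via silhouette voting.
#' @param k_range Candidate state counts.
#' @param n_perm Permutations for the group tests.
#' @param alpha Significance/FDR level.
#' @param seed Global seed; expanded to per-stage seeds internally.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(ts_dir, fiber_dir, subjects, out_dir,
                            tr = 0.645, beta = 6, window = NULL,
                            min_freq = 0.009, lambda = 0.1, k = NULL,
                            k_range = 2:6, n_perm = 5000L, alpha = 0.05,
                            seed = 1L) {
  if (is.null(window)) {
    window <- window_config(window_len = window_length_from_frequency(tr, min_freq))
  }
  structure(
    list(ts_dir = ts_dir, fiber_dir = fiber_dir, subjects = subjects,
         out_dir = out_dir, tr = tr, beta = beta, window = window,
         min_freq = min_freq, lambda = lambda, k = k, k_range = k_range,
         n_perm = check_count(n_perm, "n_perm"), alpha = alpha,
         seed = check_count(seed, "seed", min = 0L)),
    class = "pipeline_config"
  )
}

#' Run the full connectivity pipeline
#'
#' Orchestrates every stage on a cohort laid out on disk: reads the subject
#' table, computes structural DC from the fiber matrices, static DC from
#' the time series, the dynamic brain-state analysis with per-state DC,
#' permutation group tests with FDR on every DC table, and regressions of
#' the four EDE-Q subscales on the DC of significant nodes (single-modality
#' and combined), FDR-corrected across the whole family. All result tables
#' are written as TSV under `out_dir` together with a JSON run manifest
#' (configuration snapshot, package version, output checksums, per-stage
#' wall-clock).
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_invalid("`config` must be a pipeline_config")
  }
  for (d in c("ts_dir", "fiber_dir")) {
    if (!dir.exists(config[[d]])) {
      stop_invalid(sprintf("%s does not exist: %s", d, config[[d]]))
    }
  }
  if (!file.exists(config$subjects)) {
    stop_invalid(sprintf("subject table not found: %s", config$subjects))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "states"), showWarnings = FALSE)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    message(sprintf("[%s] starting", name))
    res <- force(expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    message(sprintf("[%s] done in %.1fs", name, timings[[name]]))
    res
  }

  subjects <- stage("subjects", read_subject_table(config$subjects))
  ids <- subjects$id

  struct_dc <- stage("structural", {
    rows <- lapply(ids, function(id) {
      fm <- load_fiber_matrix(file.path(config$fiber_dir, paste0("fiber_", id, ".tsv")),
                              subject_id = id)
      structural_dc(fm)$value
    })
    m <- do.call(rbind, rows)
    colnames(m) <- default_labels(ncol(m))
    m
  })

  ts_list <- stage("read_ts", lapply(ids, function(id) {
    node_time_series(read_matrix_tsv(file.path(config$ts_dir, paste0("ts_", id, ".tsv"))),
                     tr = config$tr, subject_id = id)
  }))

  static_mat <- stage("static", {
    rows <- lapply(ts_list, function(ts) static_dc(ts, beta = config$beta)$value)
    m <- do.call(rbind, rows)
    colnames(m) <- ts_list[[1]]$node_labels
    m
  })

  dyn <- stage("dynamic", dynamic_states(
    ts_list, cfg = config$window, lambda = config$lambda, k = config$k,
    k_range = config$k_range, seed = config$seed, beta = config$beta
  ))

  perm <- stage("permutation", {
    ps <- permutation_test_dc(struct_dc, subjects$group, config$n_perm,
                              config$alpha, seed = config$seed)
    pf <- permutation_test_dc(static_mat, subjects$group, config$n_perm,
                              config$alpha, seed = config$seed + 1L)
    dyn_wide <- tidyr::pivot_wider(dyn$dc, names_from = "node", values_from = "dc")
    pd <- dplyr::bind_rows(lapply(split(dyn_wide, dyn_wide$state), function(d) {
      sub <- subjects[match(d$subject, subjects$id), ]
      if (length(unique(sub$group)) < 2L || min(table(sub$group)) < 2L) return(NULL)
      res <- permutation_test_dc(d[, -(1:2)], sub$group, config$n_perm,
                                 config$alpha, seed = config$seed + 2L)
      dplyr::mutate(tidy(res), state = d$state[1], .before = 1)
    }))
    list(structural = ps, static = pf, dynamic = pd)
  })

  regress <- stage("regression", {
    sig_struct <- perm$structural$node[perm$structural$significant]
    sig_static <- perm$static$node[perm$static$significant]
    scales <- c("edeq_r", "edeq_e", "edeq_s", "edeq_w")
    fits <- list()
    add_fit <- function(set_name, preds) {
      for (sc in scales) {
        fit <- fit_edeq_regression(subjects[[sc]], preds, subjects$age)
        g <- glance(fit)
        dc_p <- tidy(fit)
        dc_p <- min(dc_p$p_value[!dc_p$term %in% c("(Intercept)", "age")])
        fits[[length(fits) + 1L]] <<- tibble::tibble(
          predictor_set = set_name, scale = sc, r_squared = g$r_squared,
          p_model = g$p_model, p_dc_min = dc_p, n = g$n)
      }
    }
    if (length(sig_struct) > 0L) {
      add_fit("structural",
              setNames(as.data.frame(struct_dc[, sig_struct, drop = FALSE]),
                       paste0("s_", sig_struct)))
    }
    if (length(sig_static) > 0L) {
      add_fit("static",
              setNames(as.data.frame(static_mat[, sig_static, drop = FALSE]),
                       paste0("f_", sig_static)))
    }
    if (length(sig_struct) > 0L && length(sig_static) > 0L) {
      add_fit("structural+static", cbind(
        setNames(as.data.frame(struct_dc[, sig_struct, drop = FALSE]),
                 paste0("s_", sig_struct)),
        setNames(as.data.frame(static_mat[, sig_static, drop = FALSE]),
                 paste0("f_", sig_static))))
    }
    if (length(fits) == 0L) {
      tibble::tibble(predictor_set = character(), scale = character(),
                     r_squared = numeric(), p_model = numeric(),
                     p_dc_min = numeric(), n = integer())
    } else {
      correct_regression_family(dplyr::bind_rows(fits), alpha = config$alpha)
    }
  })

  out <- function(name) file.path(config$out_dir, name)
  stage("write", {
    readr::write_tsv(tibble::as_tibble(cbind(id = ids, as.data.frame(struct_dc))),
                     out("dc_structural.tsv"), progress = FALSE)
    readr::write_tsv(tibble::as_tibble(cbind(id = ids, as.data.frame(static_mat))),
                     out("dc_static.tsv"), progress = FALSE)
    readr::write_tsv(dyn$dc, out("dc_dynamic.tsv"), progress = FALSE)
    readr::write_tsv(dyn$subject_assignments, out("assignments.tsv"), progress = FALSE)
    readr::write_tsv(dyn$lambdas, out("lambdas.tsv"), progress = FALSE)
    for (i in seq_len(nrow(dyn$group_states))) {
      write_matrix_tsv(dyn$group_states$mean_matrix[[i]],
                       out(sprintf("states/state_%d.tsv", i)))
    }
    readr::write_tsv(tidy(perm$structural), out("perm_structural.tsv"), progress = FALSE)
    readr::write_tsv(tidy(perm$static), out("perm_static.tsv"), progress = FALSE)
    readr::write_tsv(perm$dynamic, out("perm_dynamic.tsv"), progress = FALSE)
    readr::write_tsv(regress, out("regressions.tsv"), progress = FALSE)
    TRUE
  })

  outputs <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest <- list(
    package = "connstates",
    version = as.character(utils::packageVersion("connstates")),
    seed = config$seed,
    k = dyn$k,
    config = list(tr = config$tr, beta = config$beta,
                  window_len = config$window$window_len,
                  stride = config$window$stride,
                  taper_sigma = config$window$taper_sigma,
                  lambda = config$lambda, k_range = config$k_range,
                  n_perm = config$n_perm, alpha = config$alpha),
    checksums = as.list(tools::md5sum(outputs)),
    timings_sec = timings
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
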