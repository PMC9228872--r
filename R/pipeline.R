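# The repositioning funnel: stage-1 conformational pharmacophore screen of
# the whole library, ingestion of externally produced docking poses for the
# stage-1 passers, stage-2 in-place rescreen of those poses. Docking itself
# is out of scope by design: the contract is the pose SDF interface.

# normalise a library argument into a flat per-conformer feature table
as_feature_library <- function(x, rules, max_confs, seed) {
  if (is.data.frame(x) && "compound_id" %in% names(x) && "type" %in% names(x)) {
    ft <- as_tibble(x)
    if (!"conformer_id" %in% names(ft)) ft$conformer_id <- paste0(ft$compound_id, "/1")
    return(ft)
  }
  if (is.data.frame(x) && "mol" %in% names(x)) {
    return(featurize_library(x, rules = rules, max_confs = max_confs, seed = seed))
  }
  abort("library must be a molecule tibble or a feature table with compound_id/type columns")
}

#' Ingest externally produced docking poses
#'
#' Reads an SDF of docking poses (coordinates in the hypothesis frame),
#' record titles naming the compound. Multiple poses per compound are kept
#' (docking engines typically save up to 20); untitled records are skipped
#' with a warning.
#'
#' @param path SDF file path, or a molecule tibble already in memory.
#' @return tibble with `compound_id`, `pose_id` and list column `mol`.
#' @export
ingest_poses <- function(path) {
  if (is.data.frame(path)) {
    mols <- path
  } else {
    if (!file.exists(path)) abort(sprintf("file not found: %s", path), class = "pf_io_error")
    recs <- split_sdf_records(readLines(path, warn = FALSE))
    if (!length(recs)) {
      warn("empty pose file")
      return(tibble(compound_id = character(0), pose_id = character(0), mol = list()))
    }
    parsed <- list(); skipped <- 0L
    for (rec in recs) {
      m <- tryCatch(mol_from_sdf_lines(rec, source = basename(path)), error = function(e) NULL)
      if (is.null(m) || m$id == "unnamed") { skipped <- skipped + 1L; next }
      parsed[[length(parsed) + 1L]] <- m
    }
    if (skipped > 0) warn(sprintf("skipped %d untitled/unparseable pose record(s)", skipped))
    if (!length(parsed)) {
      warn("no usable pose records")
      return(tibble(compound_id = character(0), pose_id = character(0), mol = list()))
    }
    mols <- mols_to_tbl(parsed)
  }
  dplyr::mutate(
    dplyr::group_by(tibble(compound_id = mols$id, mol = mols$mol), .data$compound_id),
    pose_id = sprintf("%s#%d", .data$compound_id, dplyr::row_number())
  ) |> ungroup()
}

# flat pose feature table from ingest_poses() output or a ready-made table
as_pose_features <- function(poses, rules) {
  if (is.data.frame(poses) && "type" %in% names(poses)) {
    pf <- as_tibble(poses)
    if (!"pose_id" %in% names(pf)) pf$pose_id <- paste0(pf$compound_id, "#1")
    return(pf)
  }
  stopifnot(is.data.frame(poses), all(c("compound_id", "pose_id", "mol") %in% names(poses)))
  out <- list()
  for (i in seq_len(nrow(poses))) {
    ft <- perceive_features(poses$mol[[i]], rules)
    if (nrow(ft)) {
      ft$compound_id <- poses$compound_id[i]
      ft$pose_id <- poses$pose_id[i]
      out[[length(out) + 1L]] <- ft
    }
  }
  if (!length(out)) return(tibble(compound_id = character(0), pose_id = character(0)))
  bind_rows(out)
}

best_of <- function(results) {
  if (!length(results)) return(NULL)
  keys <- lapply(results, function(r) list(-r$matched_count, -r$fit_score, r$conformer_id))
  best <- 1L
  for (k in seq_along(results)[-1]) {
    if (match_key_less(keys[[k]], keys[[best]])) best <- k
  }
  results[[best]]
}

#' Stage-1 screen: conformer ensembles against a hypothesis
#'
#' Aligned (correspondence-graph) matching of every conformer of every
#' compound; per compound the best result by `(matched_count, fit_score)`.
#'
#' @param library molecule tibble or flat feature table (columns
#'   `compound_id`, `conformer_id`, feature columns).
#' @param h a `ph_hypothesis`.
#' @param min_match sites required to pass (default: all).
#' @param rules,max_confs,seed used when conformers/features must be
#'   generated from molecules.
#' @return tibble: `compound_id`, `pass`, `matched_count`, `rmsd_match`,
#'   `fit_score`, `conformer_id`.
#' @export
screen_library <- function(library, h, min_match = nrow(h$sites),
                           rules = ruleset(), max_confs = 50L, seed = 1L) {
  ft <- as_feature_library(library, rules, max_confs, seed)
  ids <- unique(ft$compound_id)
  rows <- lapply(ids, function(id) {
    sub <- ft[ft$compound_id == id, , drop = FALSE]
    res <- list()
    for (cid in unique(sub$conformer_id)) {
      conf <- sub[sub$conformer_id == cid, , drop = FALSE]
      r <- match_aligned(conf[, setdiff(names(conf), c("compound_id", "conformer_id"))],
                         h, min_match = 3L, conformer_id = cid)
      if (!is.null(r)) res[[length(res) + 1L]] <- r
    }
    b <- best_of(res)
    if (is.null(b)) {
      tibble(compound_id = id, pass = FALSE, matched_count = 0L,
             rmsd_match = NA_real_, fit_score = NA_real_, conformer_id = NA_character_)
    } else {
      tibble(compound_id = id, pass = b$matched_count >= min_match,
             matched_count = b$matched_count, rmsd_match = b$rmsd_match,
             fit_score = b$fit_score, conformer_id = b$conformer_id)
    }
  })
  bind_rows(rows)
}

#' Stage-2 screen: docking poses matched in place
#'
#' No conformational search and no realignment: the pose's own coordinates
#' in the hypothesis frame are taken as-is.
#'
#' @param poses [ingest_poses()] output or a flat pose feature table
#'   (`compound_id`, `pose_id`, feature columns).
#' @inheritParams screen_library
#' @return tibble: `compound_id`, `pass`, `matched_count`, `rmsd_match`,
#'   `fit_score`, `pose_id` (best pose per compound).
#' @export
screen_inplace <- function(poses, h, min_match = nrow(h$sites), rules = ruleset()) {
  pf <- as_pose_features(poses, rules)
  ids <- unique(pf$compound_id)
  rows <- lapply(ids, function(id) {
    sub <- pf[pf$compound_id == id, , drop = FALSE]
    res <- list()
    for (pid in unique(sub$pose_id)) {
      pose <- sub[sub$pose_id == pid, , drop = FALSE]
      r <- match_inplace(pose[, setdiff(names(pose), c("compound_id", "pose_id"))],
                         h, min_match = 1L, conformer_id = pid)
      if (!is.null(r)) res[[length(res) + 1L]] <- r
    }
    b <- best_of(res)
    if (is.null(b)) {
      tibble(compound_id = id, pass = FALSE, matched_count = 0L,
             rmsd_match = NA_real_, fit_score = NA_real_, pose_id = NA_character_)
    } else {
      tibble(compound_id = id, pass = b$matched_count >= min_match,
             matched_count = b$matched_count, rmsd_match = b$rmsd_match,
             fit_score = b$fit_score, pose_id = b$conformer_id)
    }
  })
  bind_rows(rows)
}

#' Run the two-stage screening funnel
#'
#' Stage 1 screens every library compound with conformational aligned
#' matching; only stage-1 passers are looked up in the pose set; stage 2
#' rescreens their docking poses in place. Monotone by construction:
#' `n_stage2_pass <= n_posed <= n_stage1_pass <= n_in`.
#'
#' @param library molecule tibble or flat feature table.
#' @param h a `ph_hypothesis`, or path to its JSON.
#' @param poses optional pose SDF path, [ingest_poses()] tibble, or flat
#'   pose feature table.
#' @param min_match stage-1 sites required (default: all sites).
#' @param stage2_min_match stage-2 sites required (default: same as stage
#'   1, i.e. the build tolerance is reused and all points must match
#'   again).
#' @param rules,max_confs,seed perception/conformer settings.
#' @param report optional CSV path for the per-compound report.
#' @return `ph_funnel` object: `records` (one row per compound), `counts`
#'   (named funnel counts), `params`. `tidy()` returns the records,
#'   `glance()` the counts.
#' @export
run_funnel <- function(library, h, poses = NULL, min_match = nrow(h$sites),
                       stage2_min_match = min_match, rules = ruleset(),
                       max_confs = 50L, seed = 1L, report = NULL) {
  if (is.character(h)) h <- read_hypothesis(h)
  stopifnot(inherits(h, "ph_hypothesis"))
  ft <- as_feature_library(library, rules, max_confs, seed)
  if (nrow(ft) == 0) abort("empty library", class = "pf_empty_input")
  s1 <- screen_library(ft, h, min_match = min_match)
  records <- dplyr::rename(s1, stage1_pass = "pass", stage1_count = "matched_count",
                           stage1_rmsd = "rmsd_match", stage1_fit = "fit_score",
                           stage1_conformer = "conformer_id")
  records$docked <- FALSE
  records$stage2_pass <- FALSE
  records$stage2_count <- NA_integer_
  records$stage2_rmsd <- NA_real_
  records$stage2_fit <- NA_real_
  records$stage2_pose <- NA_character_
  n_posed <- 0L
  if (!is.null(poses)) {
    pf <- as_pose_features(if (is.character(poses)) ingest_poses(poses) else poses, rules)
    if (nrow(pf)) {
      stray <- setdiff(unique(pf$compound_id), records$compound_id)
      if (length(stray)) {
        warn(sprintf("pose compound id(s) not in library: %s", paste(stray, collapse = ", ")))
      }
      passers <- records$compound_id[records$stage1_pass]
      pf <- pf[pf$compound_id %in% passers, , drop = FALSE]
      if (nrow(pf)) {
        s2 <- screen_inplace(pf, h, min_match = stage2_min_match)
        n_posed <- nrow(s2)
        for (i in seq_len(nrow(s2))) {
          k <- which(records$compound_id == s2$compound_id[i])
          records$docked[k] <- TRUE
          records$stage2_pass[k] <- s2$pass[i]
          records$stage2_count[k] <- s2$matched_count[i]
          records$stage2_rmsd[k] <- s2$rmsd_match[i]
          records$stage2_fit[k] <- s2$fit_score[i]
          records$stage2_pose[k] <- s2$pose_id[i]
        }
      }
    }
  }
  counts <- c(n_in = nrow(records), n_stage1 = sum(records$stage1_pass),
              n_posed = n_posed, n_stage2 = sum(records$stage2_pass))
  inform(sprintf("funnel: %d in -> %d stage-1 -> %d posed -> %d stage-2",
                 counts[1], counts[2], counts[3], counts[4]))
  out <- structure(list(records = records, counts = counts,
                        params = list(min_match = min_match,
                                      stage2_min_match = stage2_min_match,
                                      max_confs = max_confs, seed = seed,
                                      hypothesis = h$id)),
                   class = "ph_funnel")
  if (!is.null(report)) {
    utils::write.csv(records, report, row.names = FALSE, quote = FALSE)
  }
  out
}

#' @export
print.ph_funnel <- function(x, ...) {
  cat(sprintf("<ph_funnel> %d in -> %d stage-1 -> %d posed -> %d stage-2\n",
              x$counts[1], x$counts[2], x$counts[3], x$counts[4]))
  invisible(x)
}

#' @rdname run_funnel
#' @param x a `ph_funnel`.
#' @param ... unused.
#' @export
tidy.ph_funnel <- function(x, ...) x$records

#' @rdname run_funnel
#' @export
glance.ph_funnel <- function(x, ...) {
  tibble(n_in = x$counts[["n_in"]], n_stage1 = x$counts[["n_stage1"]],
         n_posed = x$counts[["n_posed"]], n_stage2 = x$counts[["n_stage2"]],
         min_match = x$params$min_match, stage2_min_match = x$params$stage2_min_match)
}

#' Funnel attrition plot
#'
#' Bar chart of compound counts surviving each funnel stage.
#'
#' @param object a `ph_funnel`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ph_funnel <- function(object, ...) {
  df <- tibble(stage = factor(c("library", "stage 1", "posed", "stage 2"),
                              levels = c("library", "stage 1", "posed", "stage 2")),
               n = as.integer(object$counts))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "compounds", title = "screening funnel")
}
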