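# Consensus pharmacophore hypothesis: an ordered set of typed tolerance
# spheres (sites) in a fixed receptor frame, plus the parameters it was
# built with.

canonical_site_order <- function(sites) {
  dplyr::arrange(sites, desc(.data$support), .data$type, .data$x, .data$y, .data$z)
}

#' Create a pharmacophore hypothesis
#'
#' @param sites tibble with columns `type` (codes in `A D H N P R`), `x`,
#'   `y`, `z` (angstrom), `radius` (tolerance sphere, angstrom), `support`
#'   (fraction of input ligands contributing, in (0, 1]) and optional unit
#'   direction columns `dx`, `dy`, `dz` (`NA` allowed).
#' @param id hypothesis identifier.
#' @param frame identifier of the reference frame (e.g. the PDB code of the
#'   complex whose crystal frame the sites live in).
#' @param min_fraction,tolerance the build parameters recorded with the
#'   model: minimum ligand-support fraction and clustering tolerance
#'   (angstrom).
#' @return a `ph_hypothesis` object; sites are stored in canonical order
#'   (support descending, then type, then coordinates).
#' @export
hypothesis <- function(sites, id = "hypothesis", frame = "unspecified",
                       min_fraction = 0.5, tolerance = 2.0) {
  sites <- as_tibble(sites)
  if (!all(c("dx", "dy", "dz") %in% names(sites))) {
    sites$dx <- NA_real_; sites$dy <- NA_real_; sites$dz <- NA_real_
  }
  validate_sites(sites)
  assert_scalar_number(min_fraction, "min_fraction", lower = 1e-12, upper = 1)
  assert_scalar_number(tolerance, "tolerance", lower = 1e-12)
  structure(
    list(id = id, frame = frame, sites = canonical_site_order(sites),
         build_params = list(min_fraction = min_fraction, tolerance = tolerance)),
    class = "ph_hypothesis"
  )
}

validate_sites <- function(sites) {
  need <- c("type", "x", "y", "z", "radius", "support")
  miss <- setdiff(need, names(sites))
  if (length(miss)) {
    abort(paste0("hypothesis sites missing field(s): ", paste(miss, collapse = ", ")),
          class = "pf_format_error")
  }
  if (nrow(sites) < 1) abort("a hypothesis needs at least one site", class = "pf_format_error")
  if (!all(sites$type %in% feature_type_codes)) {
    abort("site types must be drawn from {A, D, H, N, P, R}", class = "pf_format_error")
  }
  if (!all(is.finite(sites$x) & is.finite(sites$y) & is.finite(sites$z))) {
    abort("site positions must be finite", class = "pf_format_error")
  }
  if (!all(sites$radius > 0)) abort("site radius must be > 0", class = "pf_format_error")
  if (!all(sites$support > 0 & sites$support <= 1)) {
    abort("site support must be in (0, 1]", class = "pf_format_error")
  }
  has_dir <- !is.na(sites$dx)
  if (any(has_dir)) {
    nrm <- sqrt(sites$dx[has_dir]^2 + sites$dy[has_dir]^2 + sites$dz[has_dir]^2)
    if (any(abs(nrm - 1) > 1e-6)) abort("site directions must be unit vectors", class = "pf_format_error")
  }
  invisible(sites)
}

#' @export
print.ph_hypothesis <- function(x, ...) {
  cat(sprintf("<ph_hypothesis> %s [frame %s]: %d site(s) (%s); built at min_fraction %.3g, tolerance %.3g A\n",
              x$id, x$frame, nrow(x$sites), paste(sort(x$sites$type), collapse = ""),
              x$build_params$min_fraction, x$build_params$tolerance))
  print(x$sites, ...)
  invisible(x)
}

#' @rdname hypothesis
#' @param x a `ph_hypothesis`.
#' @param ... unused.
#' @export
tidy.ph_hypothesis <- function(x, ...) {
  dplyr::mutate(x$sites, site = dplyr::row_number(), .before = 1)
}

#' @rdname hypothesis
#' @export
glance.ph_hypothesis <- function(x, ...) {
  tibble(
    id = x$id, frame = x$frame, n_sites = nrow(x$sites),
    type_multiset = paste(sort(x$sites$type), collapse = ""),
    min_fraction = x$build_params$min_fraction,
    tolerance = x$build_params$tolerance,
    min_support = min(x$sites$support), max_support = max(x$sites$support)
  )
}

#' Write a hypothesis to JSON
#'
#' Schema: `{"id", "frame", "build_params": {"min_fraction", "tolerance"},
#' "sites": [{"type", "position": [x,y,z], "radius", "support",
#' "direction": [x,y,z] | null}]}`. Positions survive the round trip to full
#' double precision ([read_hypothesis()] of the written file reproduces the
#' object exactly).
#'
#' @param h a `ph_hypothesis`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hypothesis <- function(h, path) {
  stopifnot(inherits(h, "ph_hypothesis"))
  sites <- lapply(seq_len(nrow(h$sites)), function(i) {
    s <- h$sites[i, ]
    list(
      type = s$type,
      position = c(s$x, s$y, s$z),
      radius = s$radius,
      support = s$support,
      direction = if (is.na(s$dx)) NULL else c(s$dx, s$dy, s$dz)
    )
  })
  doc <- list(id = h$id, frame = h$frame, build_params = h$build_params, sites = sites)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

json_num <- function(x, field, n = 1) {
  if (is.null(x) || length(x) != n || !is.numeric(x) || any(!is.finite(x))) {
    abort(sprintf("hypothesis JSON: field '%s' missing or malformed", field),
          class = "pf_format_error")
  }
  as.numeric(x)
}

#' Read a hypothesis from JSON
#'
#' @param path path to a hypothesis JSON file (see [write_hypothesis()] for
#'   the schema). Schema violations raise a format error naming the
#'   offending field.
#' @return a `ph_hypothesis`.
#' @export
read_hypothesis <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), class = "pf_io_error")
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) abort("hypothesis JSON: unparseable document",
                                            class = "pf_format_error"))
  for (f in c("id", "frame", "build_params", "sites")) {
    if (is.null(doc[[f]])) abort(sprintf("hypothesis JSON: field '%s' missing", f),
                                 class = "pf_format_error")
  }
  if (length(doc$sites) < 1) {
    abort("hypothesis JSON: field 'sites' must contain at least one site",
          class = "pf_format_error")
  }
  sites <- bind_rows(lapply(doc$sites, function(s) {
    if (is.null(s$type) || !s$type %in% feature_type_codes) {
      abort("hypothesis JSON: field 'type' missing or invalid in a site", class = "pf_format_error")
    }
    pos <- json_num(unlist(s$position), "position", 3)
    dir <- if (is.null(s$direction)) rep(NA_real_, 3) else json_num(unlist(s$direction), "direction", 3)
    tibble(
      type = s$type, x = pos[1], y = pos[2], z = pos[3],
      radius = json_num(s$radius, "radius"),
      support = json_num(s$support, "support"),
      dx = dir[1], dy = dir[2], dz = dir[3]
    )
  }))
  hypothesis(
    sites, id = as.character(doc$id), frame = as.character(doc$frame),
    min_fraction = json_num(doc$build_params$min_fraction, "min_fraction"),
    tolerance = json_num(doc$build_params$tolerance, "tolerance")
  )
}

site_xyz <- function(h) cbind(x = h$sites$x, y = h$sites$y, z = h$sites$z)

#' Plot a hypothesis as projected tolerance spheres
#'
#' Two-dimensional projection (x-y by default) of the sites, drawn as circles
#' of their tolerance radius, coloured by feature type and labelled with
#' ligand support.
#'
#' @param object a `ph_hypothesis`.
#' @param dims which two coordinates to project onto.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ph_hypothesis <- function(object, dims = c("x", "y"), ...) {
  s <- tidy(object)
  s$u <- s[[dims[1]]]; s$v <- s[[dims[2]]]
  th <- seq(0, 2 * pi, length.out = 73)
  circles <- tidyr::unnest(
    dplyr::mutate(s, circ = purrr::pmap(list(.data$u, .data$v, .data$radius),
      function(u0, v0, r0) tibble(cu = u0 + r0 * cos(th), cv = v0 + r0 * sin(th)))),
    "circ")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$u, y = .data$v, colour = .data$type)) +
    ggplot2::geom_path(data = circles, ggplot2::aes(x = .data$cu, y = .data$cv,
                                                    group = .data$site), alpha = 0.6) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%s %.0f%%", .data$type, 100 * .data$support)),
                       vjust = -1, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(dims[1], " (Å)"), y = paste0(dims[2], " (Å)"),
                  title = sprintf("%s (%d sites)", object$id, nrow(s)), colour = "type")
}
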