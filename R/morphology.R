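#' Reduced neuron morphologies
#'
#' A morphology is a tree of cylindrical compartments. Each compartment carries
#' the geometric and passive-cable quantities needed by the integrator, a
#' region tag used for channel-density assignment and synapse placement, and
#' its path distance from the soma centre (`path_distance`, measured to the
#' distal end of the compartment; the soma itself is at 0).
#'
#' Region tags are `soma`, `dendrite_thick`, `dendrite_medium`,
#' `dendrite_thin` and `axon_initial_segment`. Dendritic calibre tags are
#' assigned by thirds of the branch length, which is how per-calibre channel
#' densities (e.g. the GPe high-voltage-activated calcium current) are mapped
#' onto the reduced geometry.
#'
#' @name morphology
NULL

.regions <- c("soma", "dendrite_thick", "dendrite_medium", "dendrite_thin",
              "axon_initial_segment")

#' Build a reduced STN or GPe morphology
#'
#' Constructs a soma plus `n_branches` unbranched tapering dendrites, each
#' discretized into `segments_per_branch` compartments. GPe cells additionally
#' receive an axon initial segment attached to the soma. The dendritic span
#' covers `[0, branch_length]` so that both proximal and distal synapse
#' placement rules are satisfiable.
#'
#' @param cell_class `"STN"` or `"GPe"`.
#' @param n_branches number of primary dendrites (default 3 for STN, 4 for GPe).
#' @param branch_length dendrite length in micrometres; must reach the distal
#'   placement threshold of 100 micrometres.
#' @param segments_per_branch compartments per dendrite (at least 2).
#' @param soma_diam soma diameter in micrometres (cylinder with L = diam).
#' @param taper dendritic diameter at origin and tip, micrometres.
#' @param passive list with `c_m` (uF/cm^2), `R_a` (ohm cm), `g_m` (S/cm^2),
#'   `E_m` (mV); defaults are standard values, overridable.
#' @return an object of class `stngpe_morphology`: a list with a
#'   `compartments` data frame and `cell_class`.
#' @export
build_reduced_morphology <- function(cell_class = c("STN", "GPe"),
                                     n_branches = if (cell_class == "GPe") 4L else 3L,
                                     branch_length = if (cell_class == "GPe") 400 else 300,
                                     segments_per_branch = 6L,
                                     soma_diam = if (cell_class == "GPe") 15 else 18.3,
                                     taper = c(2.0, 0.5),
                                     passive = list()) {
  cell_class <- match.arg(cell_class)
  stopifnot(n_branches >= 1L, segments_per_branch >= 2L, branch_length > 0)
  if (branch_length < 100)
    stop("branch_length ", branch_length,
         " um is below the distal placement threshold (100 um): ",
         "distal synapses would be unplaceable")
  pas <- utils::modifyList(list(c_m = 1, R_a = 150, g_m = 5e-5, E_m = -60),
                           passive)

  rows <- list()
  rows[[1]] <- data.frame(id = 1L, parent_id = NA_integer_,
                          length = soma_diam, diameter = soma_diam,
                          path_distance = 0, region = "soma")
  nid <- 1L
  seg_len <- branch_length / segments_per_branch
  for (b in seq_len(n_branches)) {
    parent <- 1L
    for (s in seq_len(segments_per_branch)) {
      nid <- nid + 1L
      x1 <- (s - 1) * seg_len; x2 <- s * seg_len
      mid <- (x1 + x2) / 2
      diam <- taper[1] + (taper[2] - taper[1]) * mid / branch_length
      third <- ceiling(3 * x2 / branch_length)
      region <- c("dendrite_thick", "dendrite_medium", "dendrite_thin")[min(third, 3)]
      rows[[nid]] <- data.frame(id = nid, parent_id = parent,
                                length = seg_len, diameter = diam,
                                path_distance = x2, region = region)
      parent <- nid
    }
  }
  if (cell_class == "GPe") {
    nid <- nid + 1L
    rows[[nid]] <- data.frame(id = nid, parent_id = 1L, length = 30,
                              diameter = 1, path_distance = 30,
                              region = "axon_initial_segment")
  }
  comp <- do.call(rbind, rows)
  comp$c_m <- pas$c_m; comp$R_a <- pas$R_a; comp$g_m <- pas$g_m; comp$E_m <- pas$E_m
  m <- structure(list(compartments = comp, cell_class = cell_class),
                 class = "stngpe_morphology")
  validate_morphology(m)
  m
}

validate_morphology <- function(m) {
  comp <- m$compartments
  stopifnot(all(comp$length > 0), all(comp$diameter > 0))
  roots <- which(is.na(comp$parent_id))
  if (length(roots) != 1L) stop("morphology must have exactly one root, found ",
                                length(roots))
  if (any(comp$path_distance[roots] != 0))
    stop("root (soma) compartment must have path_distance 0")
  nonroot <- comp$parent_id[!is.na(comp$parent_id)]
  if (!all(nonroot %in% comp$id)) stop("orphan parent reference in morphology")
  # tree: parent links = n - 1 and no cycles (parents resolve to root)
  if (length(nonroot) != nrow(comp) - 1L) stop("morphology is not a tree")
  invisible(m)
}

#' @export
print.stngpe_morphology <- function(x, ...) {
  comp <- x$compartments
  cat(sprintf("<stngpe_morphology> %s cell: %d compartments, max path distance %.1f um\n",
              x$cell_class, nrow(comp), max(comp$path_distance)))
  cat("  regions:", paste(sprintf("%s=%d", names(table(comp$region)),
                                  table(comp$region)), collapse = ", "), "\n")
  invisible(x)
}

#' Compartment membrane surface areas
#'
#' Lateral cylinder area pi * diameter * length, in square micrometres.
#' @param m a `stngpe_morphology`.
#' @return numeric vector of areas (um^2) in compartment order.
#' @export
compartment_areas <- function(m) {
  with(m$compartments, pi * diameter * length)
}

#' Select compartments by a named placement rule
#'
#' Placement rules are the subcellular targeting predicates of the afferent
#' projections, expressed as path-distance thresholds: cortical and
#' subthalamic glutamatergic synapses target distal dendrites (x >= 100 um),
#' pallidal GABAergic synapses target proximal regions (x < 120 um on STN
#' cells, x < 200 um on GPe cells).
#'
#' @param m a `stngpe_morphology`.
#' @param rule one of `"distal"` (x >= 100), `"proximal_stn"` (x < 120),
#'   `"proximal_gpe"` (x < 200), `"soma"`.
#' @return integer vector of compartment ids, ordered by id. Errors if the
#'   rule selects nothing (synapses must never be silently dropped).
#' @export
select_compartments <- function(m, rule = c("distal", "proximal_stn",
                                            "proximal_gpe", "soma")) {
  rule <- match.arg(rule)
  comp <- m$compartments
  dend <- comp$region %in% c("dendrite_thick", "dendrite_medium", "dendrite_thin")
  ids <- switch(rule,
    distal       = comp$id[dend & comp$path_distance >= 100],
    proximal_stn = comp$id[(dend | comp$region == "soma") & comp$path_distance < 120],
    proximal_gpe = comp$id[(dend | comp$region == "soma") & comp$path_distance < 200],
    soma         = comp$id[comp$region == "soma"])
  ids <- sort(ids)
  if (length(ids) == 0L)
    stop("placement rule '", rule, "' selects no compartments")
  ids
}

#' Read a morphology from an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`, `#` comments). SWC
#' type codes are mapped to region tags: 1 = soma, 2 = axon initial segment,
#' 3/4 = dendrite (calibre assigned by path-distance thirds). Path distances
#' are accumulated along the tree from the root using 3-D point spacing.
#'
#' @param path file path.
#' @param cell_class `"STN"` or `"GPe"`.
#' @param passive as in [build_reduced_morphology()].
#' @return a `stngpe_morphology`.
#' @export
read_swc <- function(path, cell_class = "STN", passive = list()) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty SWC file: ", path)
  fields <- strsplit(lines, "\\s+")
  if (any(lengths(fields) != 7L)) stop("SWC lines must have 7 fields")
  tab <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7, byrow = TRUE)
  if (anyNA(tab)) stop("non-numeric field in SWC file")
  colnames(tab) <- c("id", "type", "x", "y", "z", "radius", "parent")
  ids <- as.integer(tab[, "id"]); parent <- as.integer(tab[, "parent"])
  if (sum(parent == -1L) != 1L) stop("SWC must have exactly one root (parent -1)")
  idx <- match(parent, ids)
  if (any(is.na(idx) & parent != -1L)) stop("orphan parent reference in SWC")

  n <- nrow(tab)
  seglen <- numeric(n); pd <- numeric(n)
  for (i in seq_len(n)) {
    if (parent[i] == -1L) { seglen[i] <- 2 * tab[i, "radius"]; pd[i] <- 0 }
    else {
      p <- idx[i]
      if (p >= i) stop("SWC parents must precede children")
      d <- sqrt(sum((tab[i, c("x", "y", "z")] - tab[p, c("x", "y", "z")])^2))
      seglen[i] <- d
      pd[i] <- pd[p] + d
    }
  }
  pas <- utils::modifyList(list(c_m = 1, R_a = 150, g_m = 5e-5, E_m = -60),
                           passive)
  maxpd <- max(pd, 1e-9)
  region <- vapply(seq_len(n), function(i) {
    t <- tab[i, "type"]
    if (parent[i] == -1L || t == 1) "soma"
    else if (t == 2) "axon_initial_segment"
    else c("dendrite_thick", "dendrite_medium",
           "dendrite_thin")[min(ceiling(3 * pd[i] / maxpd), 3)]
  }, character(1))
  comp <- data.frame(id = seq_len(n),
                     parent_id = ifelse(parent == -1L, NA_integer_, idx),
                     length = pmax(seglen, 1e-6),
                     diameter = 2 * tab[, "radius"],
                     path_distance = pd, region = region,
                     c_m = pas$c_m, R_a = pas$R_a, g_m = pas$g_m, E_m = pas$E_m)
  m <- structure(list(compartments = comp, cell_class = cell_class),
                 class = "stngpe_morphology")
  validate_morphology(m)
  m
}

#' Write a morphology to SWC
#'
#' Inverse of [read_swc()] for unbranched-geometry morphologies: compartments
#' are laid out along straight lines so that reading the file back reproduces
#' the path distances.
#' @param m a `stngpe_morphology`.
#' @param path output file.
#' @export
write_swc <- function(m, path) {
  comp <- m$compartments
  type <- ifelse(comp$region == "soma", 1L,
                 ifelse(comp$region == "axon_initial_segment", 2L, 3L))
  # embed each compartment at x = path_distance on an axis per primary branch
  root <- which(is.na(comp$parent_id))
  branch <- integer(nrow(comp)); branch[root] <- 0L
  nb <- 0L
  for (i in seq_len(nrow(comp))) {
    if (i == root) next
    p <- comp$parent_id[i]
    if (p == root) { nb <- nb + 1L; branch[i] <- nb } else branch[i] <- branch[p]
  }
  ang <- 2 * pi * branch / max(nb, 1L)
  lines <- sprintf("%d %d %.10g %.10g %.10g %.10g %d",
                   comp$id, type,
                   comp$path_distance * cos(ang),
                   comp$path_distance * sin(ang),
                   0,
                   comp$diameter / 2,
                   ifelse(is.na(comp$parent_id), -1L, comp$parent_id))
  writeLines(c("# SWC export", lines), path)
  invisible(path)
}

#' Per-compartment summary table
#'
#' @param m a `stngpe_morphology`.
#' @return data frame with id, parent, region, path_distance (um), area (um^2).
#' @export
morphology_summary <- function(m) {
  comp <- m$compartments
  data.frame(id = comp$id, parent = comp$parent_id, region = comp$region,
             path_distance = comp$path_distance, area = compartment_areas(m))
}
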