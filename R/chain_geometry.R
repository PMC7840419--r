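#' @useDynLib tcrtails, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Define a disordered chain
#'
#' A chain is a freely jointed chain of one bead per residue (Kuhn length
#' 0.3 nm by default), anchored at a point on the membrane plane (z = 0).
#' Residues are numbered 1..`n_residues` from the membrane anchor
#' (N-terminal, juxtamembrane end); the anchor itself is bead 0.
#'
#' @param name chain name.
#' @param n_residues number of residues (= number of Kuhn segments).
#' @param sites ordered residue indices of interaction sites (tyrosines or
#'   ITAM centres), strictly increasing.
#' @param site_kind `"tyrosine"` or `"itam-center"`.
#' @param basics residue indices of basic residues (membrane-attracted).
#' @param anchor length-3 anchor coordinates; z must be 0.
#' @param kuhn_length segment length in nm.
#' @param itam_centers optional residue indices of ITAM centre sites.
#' @param meta optional list of provenance metadata.
#' @return an object of class `chain_spec`.
#' @export
chain_spec <- function(name, n_residues, sites, site_kind = "tyrosine",
                       basics = integer(), anchor = c(0, 0, 0),
                       kuhn_length = 0.3, itam_centers = integer(),
                       meta = list()) {
  n_residues <- as.integer(n_residues)
  sites <- as.integer(sites)
  basics <- as.integer(basics)
  itam_centers <- as.integer(itam_centers)
  if (length(n_residues) != 1L || is.na(n_residues) || n_residues <= 0L)
    stop("n_residues must be a positive count", call. = FALSE)
  for (fld in list(c("sites", list(sites)), c("basics", list(basics)),
                   c("itam_centers", list(itam_centers)))) {
    v <- fld[[2]]
    if (length(v) && (any(is.na(v)) || any(v < 1L) || any(v > n_residues)))
      stop(sprintf("field '%s': residue indices must lie in [1, %d]",
                   fld[[1]], n_residues), call. = FALSE)
  }
  if (length(sites) > 1L && any(diff(sites) <= 0L))
    stop("field 'sites': indices must be strictly increasing", call. = FALSE)
  if (!site_kind %in% c("tyrosine", "itam-center"))
    stop("site_kind must be 'tyrosine' or 'itam-center'", call. = FALSE)
  anchor <- as.numeric(anchor)
  if (length(anchor) != 3L || abs(anchor[3]) > 1e-12)
    stop("anchor must be a 3D point on the membrane plane (z = 0)", call. = FALSE)
  if (!is.numeric(kuhn_length) || kuhn_length <= 0)
    stop("kuhn_length must be positive", call. = FALSE)
  structure(list(name = name, n_residues = n_residues,
                 kuhn_length = kuhn_length, sites = sites,
                 site_kind = site_kind, basics = basics,
                 itam_centers = itam_centers, anchor = anchor, meta = meta),
            class = "chain_spec")
}

#' @export
print.chain_spec <- function(x, ...) {
  cat(sprintf("<chain_spec> %s: %d residues, %d %s site(s), %d basic residue(s)\n",
              x$name, x$n_residues, length(x$sites), x$site_kind,
              length(x$basics)))
  invisible(x)
}

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "tcrtails")
  if (!nzchar(p)) stop("packaged fixture not found: ", file, call. = FALSE)
  p
}

.parse_chain_record <- function(rec, source) {
  chain_spec(name = rec$name, n_residues = rec$n_residues,
             sites = unlist(rec$sites), site_kind = rec$site_kind %||% "tyrosine",
             basics = unlist(rec$basics) %||% integer(),
             kuhn_length = rec$kuhn_length %||% 0.3,
             itam_centers = unlist(rec$itam_centers) %||% integer(),
             meta = list(source = source))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a chain definition
#'
#' Loads one of the packaged TCR tail fixtures (`"zeta"`, `"epsilon"`,
#' `"delta"`, `"gamma"`) or a chain record from a YAML chain-definition file.
#'
#' @param name fixture name or path to a YAML file containing one chain
#'   record (fields `name`, `n_residues`, `sites`, `basics`, ...).
#' @return a [chain_spec()].
#' @export
load_chain_spec <- function(name) {
  if (file.exists(name)) {
    doc <- yaml::read_yaml(name)
    rec <- if (!is.null(doc$chains)) doc$chains[[1]] else doc
    return(.parse_chain_record(rec, source = name))
  }
  doc <- yaml::read_yaml(.fixture_path("chains.yaml"))
  for (rec in doc$chains) {
    if (identical(rec$name, name))
      return(.parse_chain_record(rec, source = "packaged fixture (chains.yaml)"))
  }
  stop("unknown chain: '", name, "' (packaged: ",
       paste(vapply(doc$chains, `[[`, "", "name"), collapse = ", "),
       ")", call. = FALSE)
}

#' Write chain definitions to a YAML file
#'
#' The packaged fixtures round-trip through this format.
#'
#' @param chains a `chain_spec` or list of them.
#' @param path output file.
#' @export
write_chain_yaml <- function(chains, path) {
  if (inherits(chains, "chain_spec")) chains <- list(chains)
  recs <- lapply(chains, function(ch) {
    list(name = ch$name, n_residues = ch$n_residues,
         kuhn_length = ch$kuhn_length, sites = as.list(ch$sites),
         site_kind = ch$site_kind,
         itam_centers = as.list(ch$itam_centers),
         basics = as.list(ch$basics))
  })
  yaml::write_yaml(list(chains = recs), path)
  invisible(path)
}

#' Read all chain definitions from a YAML file
#' @param path YAML file with a `chains:` list.
#' @return list of [chain_spec()] objects.
#' @export
read_chain_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  lapply(doc$chains, .parse_chain_record, source = path)
}

#' Load a ligand definition
#'
#' Packaged ligands: LCK (kinase domain, radius 2.1 nm), ZAP70 (tandem SH2,
#' 2.7 nm), CD45 (phosphatase domains, 3.4 nm).
#'
#' @param name ligand name.
#' @return list with `name`, `radius` (nm), `role`.
#' @export
load_ligand_spec <- function(name) {
  doc <- yaml::read_yaml(.fixture_path("ligands.yaml"))
  for (rec in doc$ligands) {
    if (identical(rec$name, name)) {
      if (rec$radius <= 0) stop("ligand radius must be positive", call. = FALSE)
      return(structure(rec, class = "ligand_spec"))
    }
  }
  stop("unknown ligand: ", name, call. = FALSE)
}

#' Sphere radius from molecular mass
#'
#' Radius of the sphere whose volume matches the given molecular mass at a
#' protein density of 1.41 g/cm^3.
#'
#' @param mass_kda molecular mass in kilodaltons.
#' @param density_g_cm3 protein density in g/cm^3.
#' @return radius in nm.
#' @export
radius_from_mass <- function(mass_kda, density_g_cm3 = 1.41) {
  if (any(mass_kda <= 0)) stop("mass must be positive", call. = FALSE)
  dalton_g <- 1 / 6.02214076e23
  vol_nm3 <- mass_kda * 1000 * dalton_g / (density_g_cm3 * 1e-21)
  (3 * vol_nm3 / (4 * pi))^(1 / 3)
}

#' Assemble a multi-chain receptor
#'
#' @param layout `"tcr-narrow"` (packaged structure-guided narrow layout:
#'   six anchors with 1.5 nm nearest-neighbour spacing), a list
#'   `list(type = "circle", radius = r)` placing the chains evenly on a
#'   circle, or a n_chains x 3 matrix of explicit anchor coordinates.
#' @param chains list of [chain_spec()]; for `"tcr-narrow"` defaults to the
#'   packaged six-chain TCR (2 zeta, 2 epsilon, delta, gamma).
#' @return an object of class `receptor_assembly`.
#' @export
assemble_receptor <- function(layout = "tcr-narrow", chains = NULL) {
  if (identical(layout, "tcr-narrow")) {
    doc <- yaml::read_yaml(.fixture_path("anchors_tcr_narrow_synthetic.yaml"))
    anchors <- do.call(rbind, lapply(doc$layout$anchors, as.numeric))
    if (is.null(chains))
      chains <- lapply(doc$layout$chains, load_chain_spec)
  } else if (is.list(layout) && identical(layout$type, "circle")) {
    if (is.null(chains)) stop("chains required for circle layouts", call. = FALSE)
    n <- length(chains)
    th <- 2 * pi * (seq_len(n) - 1) / n
    anchors <- cbind(layout$radius * cos(th), layout$radius * sin(th), 0)
  } else if (is.matrix(layout)) {
    if (is.null(chains)) stop("chains required for explicit layouts", call. = FALSE)
    anchors <- layout
  } else stop("unrecognised layout", call. = FALSE)
  if (nrow(anchors) != length(chains))
    stop(sprintf("chain count (%d) does not match anchor count (%d)",
                 length(chains), nrow(anchors)), call. = FALSE)
  if (any(abs(anchors[, 3]) > 1e-12))
    stop("anchors must lie on the membrane plane z = 0", call. = FALSE)
  if (nrow(anchors) > 1) {
    d <- as.matrix(stats::dist(anchors))
    if (any(d[upper.tri(d)] < 1e-9))
      stop("anchors must be pairwise distinct", call. = FALSE)
  }
  for (i in seq_along(chains)) chains[[i]]$anchor <- as.numeric(anchors[i, ])
  structure(list(chains = chains, anchors = anchors,
                 layout = if (is.character(layout)) layout else "custom"),
            class = "receptor_assembly")
}

#' @export
print.receptor_assembly <- function(x, ...) {
  cat(sprintf("<receptor_assembly> %d chain(s) [%s], %d ITAM-centre site(s)\n",
              length(x$chains),
              paste(vapply(x$chains, `[[`, "", "name"), collapse = ", "),
              sum(vapply(x$chains, function(ch) length(ch$itam_centers), 0L))))
  invisible(x)
}

# Site table for an assembly: one row per site, using ITAM centres when
# use_itam = TRUE, tyrosines otherwise. Columns: chain (index), residue.
assembly_sites <- function(assembly, use_itam = TRUE) {
  rows <- do.call(rbind, lapply(seq_along(assembly$chains), function(c) {
    ch <- assembly$chains[[c]]
    res <- if (use_itam && length(ch$itam_centers)) ch$itam_centers else ch$sites
    if (!length(res)) return(NULL)
    cbind(chain = c, residue = res)
  }))
  rows
}
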