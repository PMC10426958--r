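#' Structural connectome objects
#'
#' A structural connectome bundles a symmetric streamline-count matrix, a
#' symmetric mean tract-length matrix (mm), and per-region labels with role
#' tags (`"cortical"`, `"thalamic"`, `"cerebellar"`, `"other"`). Tract lengths
#' divided by the conduction speed give the inter-regional delays used by
#' [simulate_network()].
#'
#' @param weights n x n nonnegative symmetric matrix of streamline counts.
#' @param lengths n x n nonnegative symmetric matrix of mean tract lengths (mm).
#'   Lengths may be zero only where the corresponding weight is zero.
#' @param labels character vector of unique region names.
#' @param roles character vector of region roles, one of `"cortical"`,
#'   `"thalamic"`, `"cerebellar"`, `"other"`.
#' @param subject_id optional subject identifier.
#' @return An object of class `structural_connectome` with fields `n_regions`,
#'   `labels`, `roles`, `weights`, `lengths`, `subject_id`.
#' @export
structural_connectome <- function(weights, lengths, labels, roles,
                                  subject_id = "synthetic") {
  weights <- as.matrix(weights)
  lengths <- as.matrix(lengths)
  sc <- structure(
    list(n_regions = nrow(weights),
         labels = as.character(labels),
         roles = as.character(roles),
         weights = weights,
         lengths = lengths,
         subject_id = subject_id),
    class = "structural_connectome")
  validate_connectome(sc)
}

#' @export
print.structural_connectome <- function(x, ...) {
  cat(sprintf("Structural connectome '%s': %d regions (%s)\n",
              x$subject_id, x$n_regions,
              paste(sprintf("%d %s", table(x$roles), names(table(x$roles))),
                    collapse = ", ")))
  cat(sprintf("  weights: %d nonzero edges, max %.3g; lengths: %.1f-%.1f mm\n",
              sum(x$weights[upper.tri(x$weights)] > 0),
              max(x$weights),
              min(x$lengths[x$weights > 0]), max(x$lengths)))
  invisible(x)
}

.connectome_roles <- c("cortical", "thalamic", "cerebellar", "other")

#' Validate a structural connectome
#'
#' Checks squareness, symmetry, zero diagonals, nonnegativity, the
#' lengths-zero-implies-weight-zero rule, label uniqueness and role tags.
#' Matrices asymmetric within `tol` are symmetrized by averaging; larger
#' asymmetries are an error.
#'
#' @param sc a `structural_connectome`.
#' @param tol symmetrization tolerance on max absolute asymmetry.
#' @return the validated (possibly symmetrized) connectome, invisibly valid.
#' @export
validate_connectome <- function(sc, tol = 1e-9) {
  w <- sc$weights; l <- sc$lengths; n <- sc$n_regions
  if (n < 1) stop("connectome must contain at least one region")
  if (!is.matrix(w) || !is.matrix(l) || nrow(w) != ncol(w) ||
      !all(dim(w) == dim(l)) || nrow(w) != n)
    stop("weights and lengths must be square matrices of matching shape")
  if (length(sc$labels) != n || length(sc$roles) != n)
    stop("labels and roles must have one entry per region")
  if (anyDuplicated(sc$labels)) stop("duplicate labels")
  if (!all(sc$roles %in% .connectome_roles))
    stop("unknown role tag: roles must be one of ",
         paste(.connectome_roles, collapse = ", "))
  if (any(w < 0)) stop("negative weight entries are not allowed")
  if (any(l < 0)) stop("negative length entries are not allowed")
  for (nm in c("weights", "lengths")) {
    m <- sc[[nm]]
    asym <- max(abs(m - t(m)))
    if (asym > tol * max(1, max(abs(m))))
      stop(nm, " matrix is asymmetric beyond tolerance (max asymmetry ", asym, ")")
    sc[[nm]] <- (m + t(m)) / 2
  }
  diag(sc$weights) <- 0
  diag(sc$lengths) <- 0
  if (any(sc$lengths == 0 & sc$weights > 0 & !diag(n)))
    stop("zero tract length on an edge with positive weight")
  dimnames(sc$weights) <- dimnames(sc$lengths) <- list(sc$labels, sc$labels)
  sc
}

# sniff the delimiter of a header-free numeric matrix file
.read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

#' Read a structural connectome from delimited text files
#'
#' @param weights_path,lengths_path header-free delimited (comma, tab or
#'   whitespace) square numeric matrices: streamline counts and mean tract
#'   lengths (mm).
#' @param labels_path CSV with columns `name,role` (header optional), one row
#'   per region.
#' @param subject_id subject identifier to attach.
#' @return a validated [structural_connectome()].
#' @export
read_connectome <- function(weights_path, lengths_path, labels_path,
                            subject_id = basename(dirname(weights_path))) {
  w <- .read_matrix(weights_path)
  l <- .read_matrix(lengths_path)
  if (!file.exists(labels_path)) stop("file not found: ", labels_path)
  lab <- utils::read.csv(labels_path, header = FALSE,
                         col.names = c("name", "role"),
                         strip.white = TRUE, colClasses = "character")
  if (identical(tolower(lab$name[1]), "name")) lab <- lab[-1, , drop = FALSE]
  if (nrow(lab) != nrow(w))
    stop("labels file has ", nrow(lab), " records for ", nrow(w), " regions")
  structural_connectome(w, l, lab$name, lab$role, subject_id = subject_id)
}

#' Write a structural connectome as delimited text
#'
#' Writes `weights.txt`, `tract_lengths.txt` and `labels.txt` into `out_dir`
#' so that [read_connectome()] round-trips the object exactly.
#'
#' @param sc a `structural_connectome`.
#' @param out_dir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_connectome <- function(sc, out_dir) {
  sc <- validate_connectome(sc)
  if (sc$n_regions == 0) stop("cannot write an empty connectome")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("unwritable output directory: ", out_dir)
  paths <- c(weights = file.path(out_dir, "weights.txt"),
             lengths = file.path(out_dir, "tract_lengths.txt"),
             labels = file.path(out_dir, "labels.txt"))
  # full precision so the round-trip is bit-identical
  write.table(format(sc$weights, digits = 17, trim = TRUE, scientific = TRUE),
              paths["weights"], sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  write.table(format(sc$lengths, digits = 17, trim = TRUE, scientific = TRUE),
              paths["lengths"], sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  writeLines(paste(sc$labels, sc$roles, sep = ","), paths["labels"])
  invisible(paths)
}

#' Build a driver-region variant of a connectome
#'
#' The analysis compares three structural versions of a designated driver
#' structure (e.g. the thalamus): `parceled` keeps the individual nuclei,
#' `single` collapses them into one node, and `removed` deletes them.
#' Collapsing sums streamline counts from all merged nuclei to each other
#' region and takes the weight-weighted mean of their tract lengths
#' (unweighted mean if all merged weights to a region are zero); edges within
#' the merged group are discarded.
#'
#' @param sc a `structural_connectome`.
#' @param driver_role role tag identifying the driver group (e.g. `"thalamic"`).
#' @param mode one of `"parceled"`, `"single"`, `"removed"`.
#' @return a `structural_connectome`.
#' @export
build_variant <- function(sc, driver_role = "thalamic",
                          mode = c("parceled", "single", "removed")) {
  mode <- match.arg(mode)
  idx <- which(sc$roles == driver_role)
  if (length(idx) == 0) stop("no region with role '", driver_role, "'")
  if (mode == "parceled") return(sc)
  keep <- setdiff(seq_len(sc$n_regions), idx)
  if (mode == "removed") {
    return(structural_connectome(sc$weights[keep, keep, drop = FALSE],
                                 sc$lengths[keep, keep, drop = FALSE],
                                 sc$labels[keep], sc$roles[keep],
                                 subject_id = sc$subject_id))
  }
  # single: merged weight to k = sum of group weights; merged length =
  # weight-weighted mean of group lengths
  wg <- sc$weights[idx, keep, drop = FALSE]
  lg <- sc$lengths[idx, keep, drop = FALSE]
  w_new <- colSums(wg)
  l_new <- vapply(seq_along(keep), function(k) {
    if (w_new[k] > 0) sum(wg[, k] * lg[, k]) / w_new[k] else mean(lg[, k])
  }, numeric(1))
  n_out <- length(keep) + 1L
  w <- matrix(0, n_out, n_out)
  l <- matrix(0, n_out, n_out)
  w[seq_along(keep), seq_along(keep)] <- sc$weights[keep, keep]
  l[seq_along(keep), seq_along(keep)] <- sc$lengths[keep, keep]
  w[n_out, seq_along(keep)] <- w[seq_along(keep), n_out] <- w_new
  l[n_out, seq_along(keep)] <- l[seq_along(keep), n_out] <- l_new
  l[w == 0] <- 0
  structural_connectome(w, l,
                        c(sc$labels[keep], paste0(driver_role, "_merged")),
                        c(sc$roles[keep], driver_role),
                        subject_id = sc$subject_id)
}

#' Graph metrics of a structural connectome
#'
#' Computes, per region: degree and node strength (each normalized by its
#' maximum over regions), betweenness centrality and average shortest-path
#' length. Shortest paths use edge distances `1/w` on the max-normalized
#' weight matrix, the standard convention for streamline-count graphs, so the
#' strongest edge has unit distance. Betweenness is normalized by the number
#' of ordered node pairs excluding the node.
#'
#' @param sc a `structural_connectome`.
#' @param driver_role role tag whose group average is reported alongside the
#'   global average.
#' @return list with `per_region` (data.frame: region, role, degree, strength,
#'   betweenness, path_length), `global_average`, `driver_average` (named
#'   vectors over the four metrics) and `connected` flag. Disconnected graphs
#'   are flagged and path lengths are averaged within components.
#' @export
graph_metrics <- function(sc, driver_role = "thalamic") {
  w <- sc$weights / max(sc$weights)
  n <- sc$n_regions
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  deg <- igraph::degree(g)
  strength <- igraph::strength(g)
  dist_w <- 1 / igraph::E(g)$weight
  btw <- igraph::betweenness(g, weights = dist_w, normalized = TRUE)
  D <- igraph::distances(g, weights = dist_w)
  connected <- igraph::is_connected(g)
  if (!connected)
    warning("graph is disconnected; path lengths averaged within components")
  pl <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    mean(d[is.finite(d)])
  }, numeric(1))
  per_region <- data.frame(
    region = sc$labels, role = sc$roles,
    degree = deg / max(deg), strength = strength / max(strength),
    betweenness = btw, path_length = pl,
    stringsAsFactors = FALSE)
  avg <- function(rows) c(
    degree = mean(rows$degree), strength = mean(rows$strength),
    betweenness = mean(rows$betweenness), path_length = mean(rows$path_length))
  drv <- per_region[per_region$role == driver_role, , drop = FALSE]
  list(per_region = per_region,
       global_average = avg(per_region),
       driver_average = if (nrow(drv)) avg(drv) else NULL,
       connected = connected)
}
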