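# ---------------------------------------------------------------------------
# Trajectory post-analysis: energy drift, per-residue RMSF (with optional
# least-squares superposition), ligand-residue minimum distances and
# within-cutoff fractions, geometric hydrogen-bond detection, occupancy /
# simultaneity statistics and binned H-bond heatmap counts.
# ---------------------------------------------------------------------------

#' Construct a trajectory object
#'
#' @param times ascending frame times in ps.
#' @param coords numeric array, frames x atoms x 3, in Angstrom.
#' @param atoms data.frame with columns `atom_id`, `residue_id`,
#'   `residue_name`, `chain`, `element`, `role` (one of donor, hydrogen,
#'   acceptor, none), `ligand` (logical), and `bonded_to` (donor atom_id for
#'   hydrogens, NA otherwise).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(times, coords, atoms) {
  coords <- as.array(coords)
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3,
            dim(coords)[1] == length(times),
            dim(coords)[2] == nrow(atoms),
            all(diff(times) > 0))
  need <- c("atom_id", "residue_id", "residue_name", "chain", "element")
  stopifnot(all(need %in% names(atoms)))
  if (!"role" %in% names(atoms)) atoms$role <- "none"
  if (!"ligand" %in% names(atoms)) atoms$ligand <- FALSE
  if (!"bonded_to" %in% names(atoms)) atoms$bonded_to <- NA
  out <- list(times = as.numeric(times), coords = coords, atoms = atoms)
  class(out) <- "trajectory"
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d frames x %d atoms, %.0f-%.0f ps>\n",
              dim(x$coords)[1], dim(x$coords)[2],
              min(x$times), max(x$times)))
  invisible(x)
}

#' Total-energy drift check
#'
#' Least-squares linear fit of energy against time; reports the slope per ns,
#' the relative drift over the whole run (slope x duration / mean energy) and
#' a pass/fail verdict against a relative tolerance.
#'
#' @param energy numeric energy series.
#' @param times frame times in ps (same length, not constant).
#' @param tolerance relative-drift tolerance (default 0.01, i.e. 1%).
#' @return list with `slope_per_ns`, `relative_drift`, `pass`.
#' @export
energy_drift <- function(energy, times, tolerance = 0.01) {
  stopifnot(length(energy) == length(times))
  if (length(energy) < 10) stop("need at least 10 points")
  if (max(times) == min(times)) stop("time series is constant")
  fit <- lm(energy ~ times)
  slope <- unname(coef(fit)[2])            # per ps
  duration <- max(times) - min(times)      # ps
  rel <- slope * duration / mean(energy)
  list(slope_per_ns = slope * 1000, relative_drift = rel,
       pass = abs(rel) <= tolerance)
}

# Kabsch least-squares superposition of frame coordinates X onto reference Y
# using the rows in `fit_idx`; returns transformed X (all rows)
.superpose_frame <- function(X, Y, fit_idx) {
  P <- X[fit_idx, , drop = FALSE]
  Q <- Y[fit_idx, , drop = FALSE]
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  s <- svd(t(P0) %*% Q0)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(X, 2, pc) %*% t(R), 2, qc, `+`)
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF of residue i = sqrt(mean over frames of squared displacement from the
#' time-mean position), averaged over the residue's atoms. By default each
#' frame is first superposed onto the first frame by a least-squares rigid
#' fit over the analysed atoms, removing rigid-body drift.
#'
#' @param traj a [trajectory()].
#' @param residue_ids residues to analyse (default: all non-ligand residues).
#' @param superpose rigid-body fit each frame onto frame 1 first
#'   (default TRUE).
#' @return data.frame with `residue_id` and `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, residue_ids = NULL, superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  if (dim(traj$coords)[1] < 2) stop("need at least 2 frames")
  prot <- !traj$atoms$ligand
  if (is.null(residue_ids))
    residue_ids <- unique(traj$atoms$residue_id[prot])
  missing <- setdiff(residue_ids, traj$atoms$residue_id)
  if (length(missing))
    stop("residues absent from topology: ", paste(missing, collapse = ", "))
  sel <- which(traj$atoms$residue_id %in% residue_ids & prot)
  n_frames <- dim(traj$coords)[1]
  X <- traj$coords
  if (superpose) {
    ref <- X[1, , , drop = TRUE]
    if (is.null(dim(ref))) ref <- matrix(ref, ncol = 3)
    for (f in 2:n_frames) {
      fr <- X[f, , , drop = TRUE]
      if (is.null(dim(fr))) fr <- matrix(fr, ncol = 3)
      X[f, , ] <- .superpose_frame(fr, ref, sel)
    }
  }
  # per-atom mean position and mean squared displacement
  msd_atom <- vapply(sel, function(a) {
    P <- X[, a, , drop = TRUE]
    if (is.null(dim(P))) P <- matrix(P, ncol = 3)
    mu <- colMeans(P)
    mean(rowSums(sweep(P, 2, mu)^2))
  }, numeric(1))
  res_of_atom <- traj$atoms$residue_id[sel]
  agg <- tapply(msd_atom, res_of_atom, mean)
  out <- data.frame(residue_id = residue_ids,
                    rmsf = sqrt(unname(agg[as.character(residue_ids)])))
  rownames(out) <- NULL
  out
}

.parse_residue_label <- function(label) {
  parts <- strsplit(label, ":", fixed = TRUE)[[1]]
  if (length(parts) == 3)
    list(chain = parts[1], resname = parts[2], resid = as.integer(parts[3]))
  else if (length(parts) == 2)
    list(chain = NA, resname = parts[1], resid = as.integer(parts[2]))
  else stop("residue label must be 'chain:NAME:number' or 'NAME:number'")
}

.residue_atoms <- function(atoms, label) {
  r <- .parse_residue_label(label)
  sel <- atoms$residue_id == r$resid & toupper(atoms$residue_name) ==
    toupper(r$resname)
  if (!is.na(r$chain)) sel <- sel & atoms$chain == r$chain
  which(sel & !atoms$ligand)
}

#' Minimum ligand-residue distance per frame
#'
#' @param traj a [trajectory()].
#' @param reference_residue residue label `"chain:NAME:number"`.
#' @param ligand_atoms indices of the ligand atoms (default: atoms flagged
#'   `ligand`).
#' @return object of class `distance_series`: data.frame with `time` (ps)
#'   and `d_min` (Angstrom); the residue label in `attr(, "residue")`.
#' @export
min_distance_series <- function(traj, reference_residue,
                                ligand_atoms = which(traj$atoms$ligand)) {
  stopifnot(inherits(traj, "trajectory"))
  res_atoms <- .residue_atoms(traj$atoms, reference_residue)
  if (!length(ligand_atoms)) stop("ligand selection is empty")
  if (!length(res_atoms)) stop("residue selection is empty: ",
                               reference_residue)
  n_frames <- dim(traj$coords)[1]
  d <- vapply(seq_len(n_frames), function(f) {
    L <- matrix(traj$coords[f, ligand_atoms, ], ncol = 3)
    R <- matrix(traj$coords[f, res_atoms, ], ncol = 3)
    cross <- outer(rowSums(L^2), rowSums(R^2), `+`) - 2 * (L %*% t(R))
    sqrt(max(0, min(cross)))
  }, numeric(1))
  out <- data.frame(time = traj$times, d_min = d)
  class(out) <- c("distance_series", "data.frame")
  attr(out, "residue") <- reference_residue
  out
}

#' Fraction of frames within a distance cutoff
#'
#' Strict inequality: a frame counts when `d_min < cutoff`.
#'
#' @param series a `distance_series` (or numeric vector of distances).
#' @param cutoff distance cutoff in Angstrom (default 5).
#' @export
fraction_within <- function(series, cutoff = 5) {
  d <- if (is.data.frame(series)) series$d_min else as.numeric(series)
  stopifnot(length(d) > 0)
  mean(d < cutoff)
}

#' Kernel density estimate of a distance series
#'
#' @param series a `distance_series` (or numeric vector), >= 10 points.
#' @param bw bandwidth rule passed to [stats::density()] (default "nrd0").
#' @return a `density` object (integrates to 1 over its support).
#' @export
distance_distribution <- function(series, bw = "nrd0") {
  d <- if (is.data.frame(series)) series$d_min else as.numeric(series)
  if (length(d) < 10) stop("need at least 10 points")
  density(d, bw = bw)
}

#' Construct an H-bond existence matrix
#'
#' @param bonds data.frame with columns `donor`, `hydrogen`, `acceptor`
#'   (atom ids) and `residue` (protein-side residue label).
#' @param existence binary matrix, bonds x frames.
#' @param times optional frame times (ps).
#' @return object of class `hbond_matrix`.
#' @export
hbond_matrix <- function(bonds, existence, times = NULL) {
  existence <- as.matrix(existence)
  storage.mode(existence) <- "integer"
  stopifnot(nrow(existence) == nrow(bonds),
            all(existence %in% c(0L, 1L)))
  if (!is.null(times)) stopifnot(length(times) == ncol(existence))
  out <- list(bonds = bonds, existence = existence, times = times)
  class(out) <- "hbond_matrix"
  out
}

#' @export
print.hbond_matrix <- function(x, ...) {
  cat(sprintf("<hbond_matrix: %d bonds x %d frames>\n",
              nrow(x$existence), ncol(x$existence)))
  invisible(x)
}

#' Detect protein-ligand hydrogen bonds along a trajectory
#'
#' A candidate bond is any (donor, hydrogen, acceptor) triple with the donor
#' and acceptor on opposite sides of the protein/ligand divide and the
#' hydrogen covalently attached to the donor (`bonded_to`). The bond exists
#' in a frame iff the donor-acceptor distance is at most `r_cut` and the
#' hydrogen-donor-acceptor angle is at most `angle_cut` — both criteria are
#' pure functions of internal geometry, hence invariant under global rotation
#' and translation.
#'
#' @param traj a [trajectory()] with role annotations.
#' @param r_cut donor-acceptor distance cutoff in Angstrom (default 3.5).
#' @param angle_cut hydrogen-donor-acceptor angle cutoff in degrees
#'   (default 30).
#' @return an [hbond_matrix()].
#' @export
detect_hbonds <- function(traj, r_cut = 3.5, angle_cut = 30) {
  stopifnot(inherits(traj, "trajectory"))
  at <- traj$atoms
  donors <- which(at$role == "donor")
  acceptors <- which(at$role == "acceptor")
  if (!length(donors) || !length(acceptors))
    stop("trajectory has no donor/acceptor annotations")
  no_h <- donors[!at$atom_id[donors] %in% at$bonded_to[at$role == "hydrogen"]]
  if (length(no_h))
    stop("donor atoms without an attached hydrogen: ",
         paste(at$atom_id[no_h], collapse = ", "))
  triples <- list()
  for (d in donors) {
    hs <- which(at$role == "hydrogen" & at$bonded_to == at$atom_id[d])
    for (a in acceptors) {
      if (at$ligand[d] == at$ligand[a]) next  # only protein<->ligand bonds
      res_side <- if (at$ligand[d]) a else d
      for (h in hs) {
        triples[[length(triples) + 1L]] <- data.frame(
          donor = at$atom_id[d], hydrogen = at$atom_id[h],
          acceptor = at$atom_id[a],
          residue = paste(at$chain[res_side], at$residue_name[res_side],
                          at$residue_id[res_side], sep = ":"),
          d_idx = d, h_idx = h, a_idx = a, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(triples))
    stop("no protein-ligand donor/acceptor pairs found")
  tri <- do.call(rbind, triples)
  n_frames <- dim(traj$coords)[1]
  existence <- matrix(0L, nrow = nrow(tri), ncol = n_frames)
  coscut <- cos(angle_cut * pi / 180)
  for (f in seq_len(n_frames)) {
    D <- matrix(traj$coords[f, tri$d_idx, ], ncol = 3)
    H <- matrix(traj$coords[f, tri$h_idx, ], ncol = 3)
    A <- matrix(traj$coords[f, tri$a_idx, ], ncol = 3)
    da <- A - D
    dh <- H - D
    dist_da <- sqrt(rowSums(da^2))
    cosang <- rowSums(da * dh) / (dist_da * sqrt(rowSums(dh^2)))
    existence[, f] <- as.integer(dist_da <= r_cut & cosang >= coscut)
  }
  hbond_matrix(tri[, c("donor", "hydrogen", "acceptor", "residue")],
               existence, times = traj$times)
}

#' H-bond occupancy and simultaneity statistics
#'
#' Per-residue occupancy (fraction of frames in which any bond involving that
#' residue exists), the fraction of frames with at least one bond, and the
#' fraction with bonds to at least two distinct residues simultaneously.
#'
#' @param hbm an [hbond_matrix()].
#' @return list with `per_residue` (named occupancy fractions),
#'   `frac_any` and `frac_two_residues`.
#' @export
occupancy_stats <- function(hbm) {
  stopifnot(inherits(hbm, "hbond_matrix"), nrow(hbm$existence) > 0)
  res <- hbm$bonds$residue
  n_frames <- ncol(hbm$existence)
  by_res <- rowsum(hbm$existence, group = res) > 0  # residues x frames
  per_res <- rowMeans(by_res)
  n_res_per_frame <- colSums(by_res)
  list(per_residue = per_res,
       frac_any = mean(n_res_per_frame >= 1),
       frac_two_residues = mean(n_res_per_frame >= 2))
}

#' Binned H-bond counts for heatmap display
#'
#' Splits the run into consecutive time bins and counts, per residue and bin,
#' the number of frames in which the residue is H-bonded. Each cell is also
#' categorised as `<10`, `10-20` (bounds inclusive) or `>20`.
#'
#' @param hbm an [hbond_matrix()] with frame times.
#' @param bin_width bin width in ns; must be at least the frame spacing and
#'   divide the run length to within one frame.
#' @return list with `counts` (residues x bins integer matrix) and
#'   `category` (same shape, character).
#' @export
binned_hbond_counts <- function(hbm, bin_width) {
  stopifnot(inherits(hbm, "hbond_matrix"))
  if (is.null(hbm$times)) stop("hbond matrix carries no frame times")
  dt <- diff(hbm$times)
  spacing <- dt[1]
  bw_ps <- bin_width * 1000
  if (bw_ps < spacing) stop("bin width is smaller than the frame spacing")
  n_frames <- ncol(hbm$existence)
  frames_per_bin <- bw_ps / spacing
  if (abs(frames_per_bin - round(frames_per_bin)) > 1e-9)
    stop("bin width must be a whole number of frame spacings")
  frames_per_bin <- round(frames_per_bin)
  if (n_frames %% frames_per_bin != 0)
    stop("bin width must divide the run length exactly")
  n_bins <- n_frames %/% frames_per_bin
  bin_of <- pmin(n_bins, floor((seq_len(n_frames) - 1) / frames_per_bin) + 1)
  res <- hbm$bonds$residue
  by_res <- (rowsum(hbm$existence, group = res) > 0) * 1L
  counts <- t(rowsum(t(by_res), group = bin_of))
  colnames(counts) <- paste0("bin", seq_len(ncol(counts)))
  category <- ifelse(counts < 10, "<10",
                     ifelse(counts <= 20, "10-20", ">20"))
  dimnames(category) <- dimnames(counts)
  list(counts = counts, category = category)
}

#' Read / write a trajectory in the delimited coordinate format
#'
#' Coordinates: tab-separated columns `frame`, `time`, `atom_id`, `x`, `y`,
#' `z`; atom table: tab-separated with the [trajectory()] atom columns.
#'
#' @param traj a [trajectory()] (for writing).
#' @param coords_path,atoms_path file paths.
#' @export
write_trajectory <- function(traj, coords_path, atoms_path) {
  stopifnot(inherits(traj, "trajectory"))
  n_frames <- dim(traj$coords)[1]; n_atoms <- dim(traj$coords)[2]
  df <- data.frame(
    frame = rep(seq_len(n_frames), each = n_atoms),
    time = rep(traj$times, each = n_atoms),
    atom_id = rep(traj$atoms$atom_id, n_frames),
    x = as.vector(t(traj$coords[, , 1])),
    y = as.vector(t(traj$coords[, , 2])),
    z = as.vector(t(traj$coords[, , 3])))
  write.table(df, coords_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(traj$atoms, atoms_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(coords_path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(coords_path, atoms_path) {
  co <- read.table(coords_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  atoms <- read.table(atoms_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  frames <- sort(unique(co$frame))
  times <- vapply(frames, function(f) co$time[co$frame == f][1], numeric(1))
  n_atoms <- nrow(atoms)
  coords <- array(NA_real_, dim = c(length(frames), n_atoms, 3))
  ord <- match(co$atom_id, atoms$atom_id)
  for (k in seq_len(nrow(co))) {
    coords[co$frame[k], ord[k], ] <- c(co$x[k], co$y[k], co$z[k])
  }
  trajectory(times, coords, atoms)
}

#' Read / write an H-bond existence matrix as delimited text
#'
#' Tab-separated: columns `donor`, `hydrogen`, `acceptor`, `residue`, then
#' one 0/1 column per frame (named by time in ps when available).
#'
#' @param hbm an [hbond_matrix()] (for writing).
#' @param path file path.
#' @export
write_hbond_matrix <- function(hbm, path) {
  stopifnot(inherits(hbm, "hbond_matrix"))
  mat <- hbm$existence
  colnames(mat) <- if (!is.null(hbm$times)) paste0("t", hbm$times) else
    paste0("f", seq_len(ncol(mat)))
  df <- data.frame(hbm$bonds, mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hbond_matrix
#' @export
read_hbond_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  meta <- c("donor", "hydrogen", "acceptor", "residue")
  fcols <- setdiff(names(df), meta)
  times <- if (all(grepl("^t[0-9.eE+-]+$", fcols)))
    as.numeric(sub("^t", "", fcols)) else NULL
  hbond_matrix(df[, meta, drop = FALSE],
               as.matrix(df[, fcols, drop = FALSE]), times = times)
}
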