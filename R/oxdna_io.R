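# Readers and writers for oxDNA-format trajectories and the internal
# ensemble container.
#
# oxDNA files come in pairs: a topology (`.top`) listing strand membership and
# backbone connectivity, and a configuration (`.dat`/`.conf`) holding one or
# more frames, each with a `t = ...` header, a box line `b = ...`, an energy
# line `E = ...`, and one row per nucleotide (position, a1 versor, a3 versor,
# then velocities, which are ignored here). Positions are stored in oxDNA
# simulation units; one unit is 0.8518 nm.

#' oxDNA length unit in nm
#' @export
OXDNA_LENGTH_NM <- 0.8518

#' Read an oxDNA trajectory into a conformation ensemble
#'
#' @param topology_path path to the oxDNA topology file.
#' @param configuration_path path to the configuration/trajectory file.
#' @param duplex_map optional path to a tab-separated file with header
#'   columns `nucleotide_id` (0-based, topology order), `duplex_id`,
#'   `strand_id`, `bp_index`; required whenever the topology holds more than
#'   two strands, since staple-level origami designs cannot be paired
#'   reliably from connectivity alone.
#' @param contour_length,diameter,design_label metadata attached to each
#'   conformation; `contour_length` defaults to 0.34 nm per bp plane.
#' @return a `conformation_ensemble` with one conformation per frame.
#' @export
read_oxdna <- function(topology_path, configuration_path, duplex_map = NULL,
                       contour_length = NULL, diameter = 6,
                       design_label = "imported") {
  if (!file.exists(topology_path)) stop("topology file not found: ", topology_path)
  if (!file.exists(configuration_path))
    stop("configuration file not found: ", configuration_path)

  top_lines <- readLines(topology_path)
  if (length(top_lines) < 2)
    stop("malformed topology header at line 1 of ", topology_path,
         ": expected '<n_nucleotides> <n_strands>'")
  hdr <- suppressWarnings(as.integer(strsplit(trimws(top_lines[1]), "\\s+")[[1]]))
  if (length(hdr) < 2 || anyNA(hdr[1:2]))
    stop("malformed topology header at line 1 of ", topology_path,
         ": expected '<n_nucleotides> <n_strands>'")
  n_nuc <- hdr[1]; n_strands <- hdr[2]
  if (length(top_lines) < 1 + n_nuc)
    stop("topology declares ", n_nuc, " nucleotides but has only ",
         length(top_lines) - 1, " rows (line ", length(top_lines), ")")
  top <- do.call(rbind, lapply(seq_len(n_nuc), function(i) {
    f <- strsplit(trimws(top_lines[i + 1]), "\\s+")[[1]]
    if (length(f) < 4)
      stop("malformed topology row at line ", i + 1, " of ", topology_path)
    f[1:4]
  }))
  strand_of <- as.integer(top[, 1])

  idx <- parse_duplex_map(duplex_map, strand_of, n_strands, topology_path)

  lines <- readLines(configuration_path)
  if (length(lines) == 0) stop("empty configuration file: ", configuration_path)
  frame_len <- 3 + n_nuc
  if (length(lines) %% frame_len != 0)
    stop("count mismatch: configuration has ", length(lines),
         " lines, not a multiple of ", frame_len,
         " (3 header lines + ", n_nuc, " nucleotide rows per frame)")
  n_frames <- length(lines) %/% frame_len

  confs <- vector("list", n_frames)
  for (fr in seq_len(n_frames)) {
    off <- (fr - 1) * frame_len
    if (!grepl("^t\\s*=", lines[off + 1]))
      stop("malformed frame header at line ", off + 1,
           ": expected 't = <step>'")
    if (!grepl("^b\\s*=", lines[off + 2]))
      stop("malformed box line at line ", off + 2)
    rows <- lines[off + 3 + seq_len(n_nuc)]
    m <- matrix(suppressWarnings(
      as.numeric(unlist(strsplit(trimws(rows), "\\s+")))), nrow = n_nuc,
      byrow = TRUE)
    if (anyNA(m[, 1:9]))
      stop("malformed nucleotide row near line ", off + 4, " of ",
           configuration_path)
    nbp <- length(unique(idx$bp_index))
    confs[[fr]] <- filament_conformation(
      positions = m[, 1:3] * OXDNA_LENGTH_NM,
      base_vectors = m[, 4:6],
      normal_vectors = m[, 7:9],
      strand_id = idx$strand_id,
      duplex_id = idx$duplex_id,
      bp_index = idx$bp_index,
      n_duplex = length(unique(idx$duplex_id)),
      contour_length = contour_length %||% (0.34 * nbp),
      diameter = diameter,
      design_label = design_label
    )
  }
  conformation_ensemble(confs, provenance = list(
    source = "oxdna",
    topology = topology_path,
    configuration = configuration_path,
    duplex_map = duplex_map
  ))
}

# Resolve nucleotide -> (duplex, strand, bp) indexing, either from a user map
# or, for a plain two-strand duplex, by complementarity order (strand 2 is
# antiparallel, so its bp index runs backwards).
parse_duplex_map <- function(duplex_map, strand_of, n_strands, topology_path) {
  n_nuc <- length(strand_of)
  if (!is.null(duplex_map)) {
    if (!file.exists(duplex_map)) stop("duplex_map file not found: ", duplex_map)
    dm <- utils::read.delim(duplex_map, sep = "\t")
    need <- c("nucleotide_id", "duplex_id", "strand_id", "bp_index")
    if (!all(need %in% names(dm)))
      stop("duplex_map must have header columns: ", paste(need, collapse = ", "))
    if (nrow(dm) != n_nuc)
      stop("duplex_map rows (", nrow(dm), ") do not match topology nucleotide ",
           "count (", n_nuc, ")")
    ord <- order(dm$nucleotide_id)
    dm <- dm[ord, ]
    return(list(duplex_id = as.integer(dm$duplex_id),
                strand_id = as.integer(dm$strand_id),
                bp_index = as.integer(dm$bp_index)))
  }
  if (n_strands != 2)
    stop("duplex_map required: topology of ", topology_path, " has ",
         n_strands, " strands and pairing is ambiguous without a map")
  counts <- table(strand_of)
  if (length(counts) != 2 || counts[1] != counts[2])
    stop("cannot pair strands of unequal length without a duplex_map")
  nbp <- as.integer(counts[1])
  bp <- integer(n_nuc); st <- integer(n_nuc)
  k1 <- 0L; k2 <- 0L
  for (i in seq_len(n_nuc)) {
    if (strand_of[i] == strand_of[1]) {
      bp[i] <- k1; st[i] <- 1L; k1 <- k1 + 1L
    } else {
      bp[i] <- nbp - 1L - k2; st[i] <- 2L; k2 <- k2 + 1L
    }
  }
  list(duplex_id = rep(0L, n_nuc), strand_id = st, bp_index = bp)
}

#' Write a conformation ensemble as oxDNA topology + configuration files
#'
#' Positions are converted from nm back to oxDNA simulation units;
#' velocities are written as zeros. The inverse of [read_oxdna()] up to
#' floating-point formatting.
#'
#' @param ensemble a `conformation_ensemble`.
#' @param topology_path,configuration_path output paths.
#' @param duplex_map_path optional path to also write the duplex map TSV.
#' @param box box edge in oxDNA units written to each frame header.
#' @return invisibly, the two paths.
#' @export
write_oxdna <- function(ensemble, topology_path, configuration_path,
                        duplex_map_path = NULL, box = 1000) {
  c0 <- ensemble$conformations[[1]]
  # emit one oxDNA strand per (duplex, strand) pair, nucleotides in bp order
  ord <- order(c0$duplex_id, c0$strand_id, c0$bp_index)
  strand_code <- c0$duplex_id[ord] * 2L + c0$strand_id[ord]
  strand_oxdna <- as.integer(factor(strand_code))
  n <- length(ord)
  n3 <- integer(n); n5 <- integer(n)
  for (i in seq_len(n)) {
    n3[i] <- if (i > 1 && strand_oxdna[i - 1] == strand_oxdna[i]) i - 2L else -1L
    n5[i] <- if (i < n && strand_oxdna[i + 1] == strand_oxdna[i]) i else -1L
  }
  top <- c(paste(n, max(strand_oxdna)),
           paste(strand_oxdna, "A", n3, n5))
  writeLines(top, topology_path)

  con <- file(configuration_path, "w")
  on.exit(close(con))
  for (fr in seq_along(ensemble$conformations)) {
    cf <- ensemble$conformations[[fr]]
    p <- cf$positions[ord, , drop = FALSE] / OXDNA_LENGTH_NM
    a1 <- cf$base_vectors[ord, , drop = FALSE]
    a3 <- cf$normal_vectors[ord, , drop = FALSE]
    writeLines(c(paste("t =", fr - 1),
                 paste("b =", box, box, box),
                 "E = 0 0 0"), con)
    rows <- sprintf(paste(rep("%.12g", 15), collapse = " "),
                    p[, 1], p[, 2], p[, 3], a1[, 1], a1[, 2], a1[, 3],
                    a3[, 1], a3[, 2], a3[, 3], 0, 0, 0, 0, 0, 0)
    writeLines(rows, con)
  }
  if (!is.null(duplex_map_path)) {
    dm <- data.frame(nucleotide_id = seq_len(n) - 1L,
                     duplex_id = c0$duplex_id[ord],
                     strand_id = c0$strand_id[ord],
                     bp_index = c0$bp_index[ord])
    utils::write.table(dm, duplex_map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(topology_path, configuration_path))
}

ENSEMBLE_FORMAT_VERSION <- 1L

#' Write / read the internal ensemble container
#'
#' A single versioned container file (native R serialization) holding all
#' conformations plus provenance; the round trip is lossless, including the
#' generator seed.
#'
#' @param ensemble a `conformation_ensemble`.
#' @param path file path.
#' @return `write_ensemble` returns the path invisibly; `read_ensemble`
#'   returns the stored `conformation_ensemble`.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "conformation_ensemble"))
  saveRDS(list(format = "origamiLC_ensemble",
               version = ENSEMBLE_FORMAT_VERSION,
               ensemble = ensemble), path)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  if (!file.exists(path)) stop("ensemble file not found: ", path)
  if (file.size(path) == 0) stop("empty ensemble file: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("not an ensemble container: ", path,
                                           " (", conditionMessage(e), ")"))
  if (!is.list(obj) || !identical(obj$format, "origamiLC_ensemble"))
    stop("not an origamiLC ensemble container: ", path)
  if (!identical(obj$version, ENSEMBLE_FORMAT_VERSION))
    stop("ensemble format version mismatch: file has version ", obj$version,
         ", this build reads version ", ENSEMBLE_FORMAT_VERSION)
  obj$ensemble
}
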