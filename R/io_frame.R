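#' Read and write bilayer frames (GRO and XYZ)
#'
#' GRO files use the fixed-width GROMACS layout with positions in nm
#' (3-decimal precision; round trips are exact to 0.001 nm), residue names
#' `LIP` (lipids) and `SOL` (waters), and the box on the final line. The
#' XYZ dialect stores positions in nm with the box lengths and time stamp
#' on the comment line (`box <x> <y> <z> time_ns <t>`).
#'
#' Atom names map to particle roles through `role_map`, a named character
#' vector `c(<atom name> = <role>)`; names ending in digits fall back to
#' their alphabetic prefix (so `C1`...`C8` match the `C` entry). An atom
#' name with no mapping is an error.
#'
#' @param frame a [bilayer_frame()].
#' @param path file path.
#' @param role_map atom-name to role mapping; the default covers the
#'   generator's naming (`P`, `N`, `C*`, `OW`).
#' @return writers return `path` invisibly; readers a [bilayer_frame()].
#' @name frame_io
NULL

default_role_map <- c(P = "P", N = "N", C = "C", OW = "W")

map_roles <- function(atom_names, role_map) {
  key <- atom_names
  hit <- role_map[key]
  pref <- sub("[0-9]+$", "", key)
  hit[is.na(hit)] <- role_map[pref[is.na(hit)]]
  if (anyNA(hit))
    stop("no role mapping for atom name(s): ",
         paste(unique(key[is.na(hit)]), collapse = ", "), call. = FALSE)
  unname(hit)
}

# atom names as written: P, N, C1..Ck per lipid; OW for waters
frame_atom_names <- function(frame) {
  nm <- character(nrow(frame))
  nm[frame$role == "P"] <- "P"
  nm[frame$role == "N"] <- "N"
  nm[frame$role == "W"] <- "OW"
  ci <- which(frame$role == "C")
  if (length(ci)) {
    idx <- stats::ave(rep(1, length(ci)), frame$lipid[ci], FUN = cumsum)
    nm[ci] <- paste0("C", idx)
  }
  nm
}

#' @rdname frame_io
#' @export
write_gro <- function(frame, path) {
  b <- box_nm(frame)
  n <- nrow(frame)
  names_at <- frame_atom_names(frame)
  is_w <- frame$role == "W"
  resname <- ifelse(is_w, "SOL", "LIP")
  max_lip <- if (all(is_w)) 0L else max(frame$lipid, na.rm = TRUE)
  resid <- ifelse(is_w, max_lip + cumsum(is_w), frame$lipid)
  lines <- c(
    sprintf("synthetic bilayer frame, t= %.6f", attr(frame, "time_ns")),
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            resid %% 100000L, resname, names_at, seq_len(n) %% 100000L,
            frame$x, frame$y, frame$z),
    sprintf("%10.5f%10.5f%10.5f", b[1], b[2], b[3]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname frame_io
#' @export
read_gro <- function(path, role_map = default_role_map) {
  lines <- readLines(path)
  if (length(lines) < 4L) stop("not a GRO file: too short", call. = FALSE)
  time_ns <- 0
  tm <- regmatches(lines[1], regexpr("t=\\s*[-0-9.eE+]+", lines[1]))
  if (length(tm)) time_ns <- as.numeric(sub("t=\\s*", "", tm))
  n <- as.integer(trimws(lines[2]))
  at <- lines[3:(2 + n)]
  resid <- as.integer(substr(at, 1, 5))
  resname <- trimws(substr(at, 6, 10))
  aname <- trimws(substr(at, 11, 15))
  x <- as.numeric(substr(at, 21, 28))
  y <- as.numeric(substr(at, 29, 36))
  z <- as.numeric(substr(at, 37, 44))
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1:3]
  role <- map_roles(aname, role_map)
  lipid <- ifelse(role == "W", NA_integer_, resid)
  bilayer_frame(data.frame(x = x, y = y, z = z, role = role, lipid = lipid),
                box_nm = box, time_ns = time_ns)
}

#' @rdname frame_io
#' @export
write_xyz <- function(frame, path) {
  b <- box_nm(frame)
  # lipid-contiguous order (P, N, chain beads; waters last) so the reader
  # can rebuild lipid indices from atom order alone
  rk <- match(frame$role, c("P", "N", "C", "W"))
  frame <- frame[order(frame$role == "W", frame$lipid, rk, seq_len(nrow(frame))), ]
  lines <- c(
    sprintf("%d", nrow(frame)),
    sprintf("box %.6f %.6f %.6f time_ns %.6f", b[1], b[2], b[3],
            attr(frame, "time_ns")),
    sprintf("%-4s %12.6f %12.6f %12.6f", frame_atom_names(frame),
            frame$x, frame$y, frame$z))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname frame_io
#' @export
read_xyz <- function(path, role_map = default_role_map) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  hdr <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  bi <- match("box", hdr)
  if (is.na(bi)) stop("XYZ comment line lacks 'box <x> <y> <z>'", call. = FALSE)
  box <- as.numeric(hdr[bi + 1:3])
  ti <- match("time_ns", hdr)
  time_ns <- if (is.na(ti)) 0 else as.numeric(hdr[ti + 1])
  at <- do.call(rbind, strsplit(trimws(lines[3:(2 + n)]), "\\s+"))
  role <- map_roles(at[, 1], role_map)
  # reconstruct lipid indices: a P starts a new lipid; N and C beads follow
  lipid <- rep(NA_integer_, n)
  lipid[role != "W"] <- cumsum(role[role != "W"] == "P")
  bilayer_frame(data.frame(x = as.numeric(at[, 2]), y = as.numeric(at[, 3]),
                           z = as.numeric(at[, 4]), role = role, lipid = lipid),
                box_nm = box, time_ns = time_ns)
}
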