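#' Write a scattering dataset to a Touchstone file
#'
#' Touchstone v1 text format (`.s8p` for 8 ports), real/imaginary data,
#' 50 Ohm reference, frequencies in Hz: one block per frequency point,
#' S-matrix in row-major order, four complex pairs per line.
#'
#' @param ds A [scattering_dataset()].
#' @param path Output file path (conventionally `.sNp` with N the port
#'   count).
#' @return Invisibly, `path`.
#' @export
write_touchstone <- function(ds, path) {
  stopifnot(inherits(ds, "scattering_dataset"))
  p <- dim(ds$s)[1]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("! ", p, "-port S-parameters, scenario: ",
                      ds$scenario),
               "# Hz S RI R 50"), con)
  fmt <- function(x) formatC(x, format = "e", digits = 12)
  for (fi in seq_along(ds$frequencies)) {
    m <- as.vector(t(ds$s[, , fi]))               # row-major element order
    vals <- rbind(Re(m), Im(m))                   # 2 x p^2 Re/Im pairs
    pieces <- apply(vals, 2, function(v) paste(fmt(v[1]), fmt(v[2])))
    groups <- split(pieces, ceiling(seq_along(pieces) / 4))
    lines <- vapply(groups, paste, "", collapse = " ")
    lines[1] <- paste(formatC(ds$frequencies[fi], format = "f",
                              digits = 0), lines[1])
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a Touchstone file into a scattering dataset
#'
#' Supports version-1 files with real/imaginary (`RI`) S-parameter data
#' and any frequency unit (`HZ`, `KHZ`, `MHZ`, `GHZ`); comment lines
#' (`!`) are ignored. The port count is inferred from the token count.
#'
#' @param path Touchstone file path.
#' @param scenario Optional scenario label to attach.
#' @return A [scattering_dataset()].
#' @export
read_touchstone <- function(path, scenario = NA) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("!.*$", "", lines)
  opt <- grep("^\\s*#", lines, value = TRUE)
  if (!length(opt)) stop_mw("config error: no Touchstone option line")
  toks <- toupper(strsplit(trimws(sub("^\\s*#", "", opt[1])), "\\s+")[[1]])
  unit <- c(HZ = 1, KHZ = 1e3, MHZ = 1e6, GHZ = 1e9)[
    intersect(toks, c("HZ", "KHZ", "MHZ", "GHZ"))[1]]
  if (is.na(unit)) unit <- 1e9  # Touchstone default
  if (!"RI" %in% toks)
    stop_mw("config error: only RI-format Touchstone files are supported")
  dat <- lines[!grepl("^\\s*#", lines)]
  nums <- as.numeric(unlist(strsplit(trimws(paste(dat, collapse = " ")),
                                     "\\s+")))
  nums <- nums[!is.na(nums)]
  ## block length per frequency: 1 + 2*p^2; infer p from total count
  p <- NA
  for (cand in 1:64) {
    if (length(nums) %% (1 + 2 * cand^2) == 0) {
      blk <- matrix(nums, nrow = 1 + 2 * cand^2)
      if (all(diff(blk[1, ]) > 0) || ncol(blk) == 1) { p <- cand; break }
    }
  }
  if (is.na(p)) stop_mw("config error: cannot infer port count from file")
  blk <- matrix(nums, nrow = 1 + 2 * p^2)
  freqs <- blk[1, ] * unit
  s <- array(0i, dim = c(p, p, ncol(blk)))
  for (fi in seq_len(ncol(blk))) {
    v <- blk[-1, fi]
    cm <- matrix(v[seq(1, length(v), 2)] + 1i * v[seq(2, length(v), 2)],
                 nrow = p, byrow = TRUE)
    s[, , fi] <- cm
  }
  scattering_dataset(s, freqs, scenario)
}

#' Exchange incident fields as long-format CSV
#'
#' Text container for incident fields, usable to feed externally computed
#' (e.g. full-wave) fields into the imaging chain: one row per (node,
#' antenna, frequency) with columns `frequency_hz`, `antenna`, `node`,
#' `re_ex`, `im_ex`, `re_ey`, `im_ey`, `re_ez`, `im_ez`. Node indices
#' follow the grid's x-fastest linear ordering.
#'
#' @param fields An [incident_field_set()].
#' @param path CSV output path.
#' @return Invisibly, `path`.
#' @export
write_field_csv <- function(fields, path) {
  rows <- list()
  for (fi in seq_along(fields$frequencies)) {
    E <- fields$fields[[fi]]
    for (p in seq_len(dim(E)[3])) {
      rows[[length(rows) + 1]] <- data.frame(
        frequency_hz = fields$frequencies[fi], antenna = p,
        node = seq_len(dim(E)[1]),
        re_ex = Re(E[, 1, p]), im_ex = Im(E[, 1, p]),
        re_ey = Re(E[, 2, p]), im_ey = Im(E[, 2, p]),
        re_ez = Re(E[, 3, p]), im_ez = Im(E[, 3, p]))
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @param grid The [roi_grid()] the fields refer to.
#' @param array The matching [array_geometry()].
#' @param background The coupling-medium material.
#' @export
read_field_csv <- function(path, grid, array, background) {
  df <- utils::read.csv(path)
  freqs <- sort(unique(df$frequency_hz))
  nant <- max(df$antenna)
  fields <- lapply(freqs, function(f) {
    E <- array(0i, dim = c(grid$n_nodes, 3, nant))
    sub <- df[df$frequency_hz == f, ]
    for (p in seq_len(nant)) {
      sp <- sub[sub$antenna == p, ]
      sp <- sp[order(sp$node), ]
      if (nrow(sp) != grid$n_nodes)
        stop_mw("contract error: field file misses nodes for antenna ", p)
      E[, 1, p] <- sp$re_ex + 1i * sp$im_ex
      E[, 2, p] <- sp$re_ey + 1i * sp$im_ey
      E[, 3, p] <- sp$re_ez + 1i * sp$im_ez
    }
    E
  })
  structure(list(fields = fields, frequencies = freqs, grid = grid,
                 array = array, background = background),
            class = "incident_field_set")
}
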