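#' Lattice state of the adhesion system
#'
#' An L x L periodic square lattice holding the membrane-substrate
#' separation field `l` (nm) and three binary composition fields: receptors
#' `m_plus` on the upper (cell) membrane, ligands `m_minus` on the lower
#' surface, and raft patches `n_plus` on the upper membrane. Fields are
#' stored column-major (site `i` has row `(i-1) %% L + 1`, column
#' `(i-1) %/% L + 1`).
#'
#' @param L Linear lattice size in patches.
#' @param l0 Initial uniform separation, nm (default: binding-well centre
#'   would be set by the caller; here 15 nm).
#' @param ligands_mobile Logical; whether lower-surface ligands hop.
#' @return An object of class `lattice_state`.
#' @export
lattice_state <- function(L, l0 = 15, ligands_mobile = TRUE) {
  stopifnot(L >= 2, l0 >= 0)
  structure(list(L = as.integer(L),
                 l = rep(as.numeric(l0), L * L),
                 m_plus = integer(L * L),
                 m_minus = integer(L * L),
                 n_plus = integer(L * L),
                 ligands_mobile = isTRUE(ligands_mobile)),
            class = "lattice_state")
}

#' Validate a lattice state
#'
#' Checks the structural invariants: field lengths equal `L^2`, all
#' separations non-negative, occupancies binary.
#'
#' @param state A `lattice_state`.
#' @return The state, invisibly; errors on violation.
#' @export
validate_state <- function(state) {
  stopifnot(inherits(state, "lattice_state"))
  N <- state$L^2
  if (length(state$l) != N || length(state$m_plus) != N ||
      length(state$m_minus) != N || length(state$n_plus) != N)
    stop("field length mismatch with L^2")
  if (any(state$l < 0)) stop("separation field has l < 0")
  for (f in c("m_plus", "m_minus", "n_plus"))
    if (!all(state[[f]] %in% c(0L, 1L)))
      stop(sprintf("%s is not binary", f))
  invisible(state)
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("lattice_state: %d x %d patches (%s ligands)\n",
              x$L, x$L, if (x$ligands_mobile) "mobile" else "immobile"))
  cat(sprintf("  receptors: %d, ligands: %d, rafts: %d\n",
              sum(x$m_plus), sum(x$m_minus), sum(x$n_plus)))
  cat(sprintf("  separation: mean %.3f nm, range [%.3f, %.3f]\n",
              mean(x$l), min(x$l), max(x$l)))
  invisible(x)
}

#' Neighbouring site under periodic boundaries
#'
#' @param L Lattice size.
#' @param site 1-based site index (column-major).
#' @param direction One of `"right"`, `"left"`, `"down"`, `"up"` (column
#'   +1/-1, row +1/-1) or an integer 1:4 in that order.
#' @return The 1-based neighbour index.
#' @export
neighbor_site <- function(L, site, direction) {
  dirs <- c("right", "left", "down", "up")
  if (is.character(direction)) direction <- match(direction, dirs)
  stopifnot(!is.na(direction), direction %in% 1:4,
            site >= 1, site <= L * L)
  L <- as.integer(L)
  i <- as.integer(site) - 1L
  r <- i %% L
  cc <- i %/% L
  switch(direction,
         ((cc + 1L) %% L) * L + r + 1L,
         ((cc - 1L + L) %% L) * L + r + 1L,
         cc * L + (r + 1L) %% L + 1L,
         cc * L + (r - 1L + L) %% L + 1L)
}

#' Write a lattice state snapshot to a plain-text file
#'
#' Lossless round-trip serialization: separations are written with 17
#' significant digits, occupancies as 0/1 strings. Model parameters are
#' stored as metadata when supplied.
#'
#' @param state A `lattice_state`.
#' @param path Output file path.
#' @param params Optional `model_params` stored as metadata.
#' @return `path`, invisibly.
#' @export
write_state <- function(state, path, params = NULL) {
  validate_state(state)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# raftadhesion lattice_state v1", con)
  writeLines(sprintf("L %d", state$L), con)
  writeLines(sprintf("ligands_mobile %d", as.integer(state$ligands_mobile)),
             con)
  if (!is.null(params)) {
    pl <- as_param_list(params)
    writeLines(sprintf("params %s",
                       paste(sprintf("%s=%.17g", names(pl), unlist(pl)),
                             collapse = " ")), con)
  }
  writeLines(sprintf("l %s", paste(sprintf("%.17g", state$l),
                                   collapse = " ")), con)
  writeLines(sprintf("m_plus %s", paste(state$m_plus, collapse = "")), con)
  writeLines(sprintf("m_minus %s", paste(state$m_minus, collapse = "")), con)
  writeLines(sprintf("n_plus %s", paste(state$n_plus, collapse = "")), con)
  invisible(path)
}

#' Read a lattice state snapshot written by [write_state()]
#'
#' @param path File path.
#' @return A list with elements `state` (`lattice_state`) and `params`
#'   (`model_params` or `NULL`).
#' @export
read_state <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  kv <- function(key) {
    ln <- lines[startsWith(lines, paste0(key, " "))]
    if (length(ln) != 1) stop(sprintf("missing field '%s' in %s", key, path))
    sub(paste0("^", key, " "), "", ln)
  }
  L <- as.integer(kv("L"))
  st <- lattice_state(L)
  st$ligands_mobile <- as.integer(kv("ligands_mobile")) == 1L
  st$l <- as.numeric(strsplit(kv("l"), " ", fixed = TRUE)[[1]])
  bits <- function(key)
    as.integer(strsplit(kv(key), "", fixed = TRUE)[[1]])
  st$m_plus <- bits("m_plus")
  st$m_minus <- bits("m_minus")
  st$n_plus <- bits("n_plus")
  validate_state(st)
  params <- NULL
  pl <- lines[startsWith(lines, "params ")]
  if (length(pl) == 1) {
    parts <- strsplit(sub("^params ", "", pl), " ", fixed = TRUE)[[1]]
    vals <- as.numeric(sub("^[^=]+=", "", parts))
    names(vals) <- sub("=.*$", "", parts)
    params <- do.call(model_params, as.list(vals))
  }
  list(state = st, params = params)
}
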