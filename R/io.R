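# Trajectory I/O: snapshots stored as JSON at full IEEE precision so a
# write/read round trip reproduces coordinates exactly.

#' Write a trajectory to disk
#'
#' Stores snapshots (per-vertex coordinates in nm, arm binding state) with
#' optional topology metadata from the state (element types, connectivity,
#' binding occupancy), as a single JSON document at full floating-point
#' precision.
#'
#' @param snapshots snapshot list from [advance()].
#' @param path output file path (`.json`).
#' @param state optional `actomyo_state` whose topology is embedded.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(snapshots, path, state = NULL) {
  if (!length(snapshots)) stop("need at least one snapshot")
  doc <- list(
    format = "actomyosim-trajectory",
    version = 1L,
    n_snapshots = length(snapshots),
    topology = if (is.null(state)) NULL else list(
      params = unclass(state$params),
      vtype = state$vtype,
      clamped = state$clamped,
      bonds = state$bonds,
      angles = state$angles,
      fils = state$fils,
      seg = state$seg,
      acps = state$acps,
      arms = state$arms[c("motor", "anchor", "side", "wfrom", "wto")],
      n_motors = length(state$motors),
      occ = as.integer(state$occ),
      occ_dim = dim(state$occ),
      box = state$box,
      bkind = state$bkind
    ),
    snapshots = lapply(snapshots, function(s) list(
      time = s$time,
      pos = s$pos,
      arm_bound = s$arms$bound,
      arm_seg = s$arms$seg,
      arm_site = s$arms$site
    ))
  )
  # I(17) = 17 significant digits: doubles survive the decimal round trip
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path file path.
#' @return list with `topology` (or `NULL`) and `snapshots`, each snapshot
#'   holding `time`, `pos` (matrix, nm) and `arms` (data frame).
#' @export
read_trajectory <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "actomyosim-trajectory"))
    stop("not an actomyosim trajectory file")
  num <- function(x) vapply(x, function(v) if (is.null(v)) NA_real_ else
    as.numeric(v), 0)
  out <- lapply(doc$snapshots, function(s) {
    pos <- do.call(rbind, lapply(s$pos, num))
    list(time = as.numeric(s$time),
         pos = pos,
         arms = data.frame(
           bound = as.logical(num(s$arm_bound)),
           seg = as.integer(num(s$arm_seg)),
           site = as.integer(num(s$arm_site))))
  })
  list(topology = doc$topology, snapshots = out)
}

#' Rebuild a measurable state from a trajectory file
#'
#' Reconstructs an `actomyo_state` (topology, parameters and the final
#' snapshot's positions and arm bindings) from a trajectory written with
#' its `state` argument, so cross-section measurement can be re-run
#' without the original session.
#'
#' @param traj result of [read_trajectory()], or a file path.
#' @return An `actomyo_state` positioned at the last snapshot.
#' @export
state_from_trajectory <- function(traj) {
  if (is.character(traj)) traj <- read_trajectory(traj)
  top <- traj$topology
  if (is.null(top)) stop("trajectory was written without topology")
  vec <- function(x) unlist(x, use.names = FALSE)
  # data frames serialize as arrays of row objects
  df <- function(x) {
    if (!length(x)) return(data.frame())
    do.call(rbind, lapply(x, function(r)
      as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                    stringsAsFactors = FALSE)))
  }
  p <- lapply(top$params, function(v) vec(v))
  class(p) <- "actomyo_params"
  last <- traj$snapshots[[length(traj$snapshots)]]
  st <- list(
    params = p,
    box = vec(top$box),
    bkind = as.integer(vec(top$bkind)),
    pos = last$pos,
    vtype = as.integer(vec(top$vtype)),
    clamped = as.logical(vec(top$clamped)),
    bonds = df(top$bonds),
    angles = df(top$angles),
    fils = lapply(top$fils, function(v) as.integer(vec(v))),
    seg = df(top$seg),
    occ = matrix(as.integer(vec(top$occ)), vec(top$occ_dim)[1],
                 vec(top$occ_dim)[2]),
    arms = cbind(df(top$arms), last$arms),
    motors = replicate(as.integer(vec(top$n_motors)), list(), simplify = FALSE),
    acps = df(top$acps),
    time = last$time,
    warnings = character(0)
  )
  class(st) <- "actomyo_state"
  st
}
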