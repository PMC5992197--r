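#' Y-maze geometry
#'
#' The maze skeleton used throughout: a central choice point at the origin
#' with three straight arms separated by 120 degrees. The departure (start)
#' arm points down; the left and right goal arms point up-left and up-right.
#' Arms are 85 cm long, so the return path from a goal-arm end back to the
#' start-arm beginning measures 170 cm through the choice point.
#'
#' @param arm_length_cm arm length in cm (default 85).
#' @return list with \code{arm_length_cm} and unit vectors \code{u_start},
#'   \code{u_left}, \code{u_right} plus the landmark coordinates
#'   \code{start_pos}, \code{goal_left}, \code{goal_right} (2-vectors, cm).
#' @export
maze_geometry <- function(arm_length_cm = 85) {
  u_start <- c(0, -1)
  u_left <- c(cos(150 * pi / 180), sin(150 * pi / 180))
  u_right <- c(cos(30 * pi / 180), sin(30 * pi / 180))
  list(arm_length_cm = arm_length_cm,
       u_start = u_start, u_left = u_left, u_right = u_right,
       start_pos = arm_length_cm * u_start,
       goal_left = arm_length_cm * u_left,
       goal_right = arm_length_cm * u_right)
}

# Project points onto one arm segment (origin -> len*u); returns the
# along-arm coordinate (clamped to [0, len]) and the perpendicular distance.
project_on_arm <- function(x, y, u, len) {
  s <- pmin(pmax(x * u[1] + y * u[2], 0), len)
  px <- s * u[1]; py <- s * u[2]
  list(s = s, d = sqrt((x - px)^2 + (y - py)^2))
}

#' Map tracked positions to linearised return-path coordinates
#'
#' Projects each (x, y) sample onto the maze skeleton and expresses it as a
#' distance along the return path of the given goal arm: 0 at the goal-arm
#' end, \code{arm_length} at the choice point, \code{2*arm_length} at the
#' start-arm beginning. Samples nearer to the opposite goal arm, or farther
#' than \code{tol_cm} from the skeleton, get \code{NA}.
#'
#' @param x,y numeric vectors of positions, cm.
#' @param goal_arm "left" or "right": which goal arm anchors the path.
#' @param geometry a [maze_geometry()] list.
#' @param tol_cm maximum perpendicular distance from the skeleton (default
#'   10 cm) beyond which a sample is treated as off-maze.
#' @return numeric vector of path coordinates in cm (NA when off-path).
#' @export
linearise_path <- function(x, y, goal_arm, geometry = maze_geometry(),
                           tol_cm = 10) {
  stopifnot(goal_arm %in% c("left", "right"))
  if (geometry$arm_length_cm <= 0) stop("degenerate maze skeleton")
  len <- geometry$arm_length_cm
  u_goal <- if (goal_arm == "left") geometry$u_left else geometry$u_right
  u_other <- if (goal_arm == "left") geometry$u_right else geometry$u_left
  pg <- project_on_arm(x, y, u_goal, len)
  ps <- project_on_arm(x, y, geometry$u_start, len)
  po <- project_on_arm(x, y, u_other, len)
  s <- ifelse(pg$d <= ps$d, len - pg$s, len + ps$s)
  d <- pmin(pg$d, ps$d)
  s[po$d < d | d > tol_cm] <- NA_real_
  s
}

#' Assign linearised positions to five equal maze sections
#'
#' The return path is divided into five equal-length sections: section 1 is
#' the goal-arm end (reward site), section 3 is centred on the choice point,
#' section 5 is the start-arm beginning where the next trial begins.
#'
#' @param path_cm linearised coordinates from [linearise_path()].
#' @param geometry a [maze_geometry()] list.
#' @return integer vector of section ids 1..5 (NA propagates).
#' @export
maze_section <- function(path_cm, geometry = maze_geometry()) {
  total <- 2 * geometry$arm_length_cm
  sec <- pmin(5L, as.integer(floor(path_cm / (total / 5))) + 1L)
  sec
}

#' Per-sample maze sections for every ITI of a session
#'
#' @param session a \code{maze_session}.
#' @param geometry,tol_cm passed to [linearise_path()].
#' @return data frame \code{iti}, \code{time_s}, \code{section} with one row
#'   per tracking sample falling inside an ITI.
#' @export
linearise <- function(session, geometry = maze_geometry(), tol_cm = 10) {
  tr <- session$tracking
  out <- lapply(seq_len(nrow(session$itis)), function(t) {
    it <- session$itis[t, ]
    idx <- which(tr$time_s >= it$t_start_s & tr$time_s < it$t_end_s)
    if (!length(idx)) return(NULL)
    s <- linearise_path(tr$x_cm[idx], tr$y_cm[idx],
                        session$trials$arm[t], geometry, tol_cm)
    data.frame(iti = t, time_s = tr$time_s[idx],
               section = maze_section(s, geometry))
  })
  do.call(rbind, out)
}
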