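#' Rigid world-space transform
#'
#' A rigid transform acting on world coordinates (mm):
#' `T(x) = R (x - center) + center + translation`, with
#' `R = Rz(rz) %*% Ry(ry) %*% Rx(rx)` and angles in degrees
#' (extrinsic x-y-z Euler convention). The identity transform has all six
#' parameters zero for any center.
#'
#' @param rotation numeric(3), rotations about the world x, y, z axes (degrees)
#' @param translation numeric(3), translation (mm)
#' @param center numeric(3), rotation center in world coordinates (mm)
#' @return an object of class `rigid_transform`
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotation) == 3, length(translation) == 3,
            length(center) == 3,
            all(is.finite(c(rotation, translation, center))))
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

rotation_matrix_zyx <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

#' 4x4 homogeneous matrix of a rigid transform
#' @param t a `rigid_transform`
#' @return 4x4 matrix mapping homogeneous world coordinates
#' @export
rigid_matrix <- function(t) {
  r <- rotation_matrix_zyx(t$rotation)
  m <- diag(4)
  m[1:3, 1:3] <- r
  m[1:3, 4] <- t$center + t$translation - r %*% t$center
  m
}

#' Recover rigid parameters from a 4x4 rigid matrix
#' @param m 4x4 rigid homogeneous matrix
#' @param center rotation center to express the parameters about
#' @return a `rigid_transform`
#' @export
rigid_from_matrix <- function(m, center = c(0, 0, 0)) {
  r <- m[1:3, 1:3]
  ry <- asin(max(-1, min(1, -r[3, 1])))
  if (abs(cos(ry)) > 1e-8) {
    rx <- atan2(r[3, 2], r[3, 3])
    rz <- atan2(r[2, 1], r[1, 1])
  } else {  # gimbal lock: fold x into z
    rx <- atan2(-r[2, 3], r[2, 2])
    rz <- 0
  }
  rot <- c(rx, ry, rz) * 180 / pi
  tr <- m[1:3, 4] - center + r %*% center
  rigid_transform(rot, as.numeric(tr), center)
}

#' Compose two rigid transforms (`a` after `b`)
#' @param a,b `rigid_transform` objects
#' @return the composition as a `rigid_transform` (center taken from `a`)
#' @export
compose_rigid <- function(a, b) {
  rigid_from_matrix(rigid_matrix(a) %*% rigid_matrix(b), a$center)
}

#' Invert a rigid transform
#' @param t a `rigid_transform`
#' @return the inverse `rigid_transform` about the same center
#' @export
invert_rigid <- function(t) {
  rigid_from_matrix(solve(rigid_matrix(t)), t$center)
}

#' Geodesic angle (degrees) between the rotations of two rigid transforms
#' @param a,b `rigid_transform` objects
#' @return rotation distance in degrees
#' @export
rotation_distance <- function(a, b) {
  ra <- rigid_matrix(a)[1:3, 1:3]
  rb <- rigid_matrix(b)[1:3, 1:3]
  tr <- sum(diag(t(ra) %*% rb))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid transform: rot (deg) [%s]  trans (mm) [%s]\n",
              paste(sprintf("%.3f", x$rotation), collapse = ", "),
              paste(sprintf("%.3f", x$translation), collapse = ", ")))
  invisible(x)
}
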