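#' @include geometry.R
NULL

#' Create a pose Kalman filter
#'
#' Error-state Kalman filter for a stream of rigid poses under a
#' constant-pose process model: the translation is filtered linearly, the
#' orientation multiplicatively on the rotation-vector error state. The first
#' measurement initialises the mean.
#'
#' @param processNoise `(mm^2/frame, rad^2/frame)` added to the covariances at
#'   each predict step. Default `0.1` mm^2 and `0.01` deg^2 (converted to
#'   rad^2).
#' @param measurementNoise `(mm^2, rad^2)` of one pose measurement; the
#'   translation part may be overridden per update (e.g. from ICP residuals).
#' @return A [PoseFilterState-class].
#' @export
poseFilter <- function(processNoise = c(0.1, (0.01) * (pi / 180)^2),
                       measurementNoise = c(4, (0.5 * pi / 180)^2)) {
  new("PoseFilterState",
      translation = c(0, 0, 0), Pt = diag(3) * 1e6,
      quaternion = c(1, 0, 0, 0), Pq = diag(3) * 10,
      processNoise = as.numeric(processNoise),
      measurementNoise = as.numeric(measurementNoise),
      initialized = FALSE)
}

#' Absorb one pose measurement into the filter
#'
#' Predict (inflate covariances by the process noise) and correct with the
#' measured pose. The measured quaternion is hemisphere-aligned with the state
#' before the multiplicative update, and the state quaternion is renormalised
#' afterwards.
#'
#' @param state a [PoseFilterState-class].
#' @param measurement a [RigidTransform-class] pose measurement.
#' @param measurementNoise optional `(mm^2, rad^2)` override for this update;
#'   `NA` entries keep the filter's default.
#' @return The updated [PoseFilterState-class].
#' @export
kalmanUpdate <- function(state, measurement, measurementNoise = c(NA, NA)) {
  m <- transformMatrix(measurement)
  zt <- m[1:3, 4]
  zq <- rotationToQuaternion(m[1:3, 1:3])
  rn <- state@measurementNoise
  ov <- as.numeric(measurementNoise)
  if (length(ov) >= 1 && !is.na(ov[1])) rn[1] <- ov[1]
  if (length(ov) >= 2 && !is.na(ov[2])) rn[2] <- ov[2]
  if (!state@initialized) {
    state@translation <- zt
    state@quaternion <- zq
    state@Pt <- diag(3) * rn[1]
    state@Pq <- diag(3) * rn[2]
    state@initialized <- TRUE
    return(state)
  }
  # predict: constant pose, covariance inflation
  Pt <- state@Pt + diag(3) * state@processNoise[1]
  Pq <- state@Pq + diag(3) * state@processNoise[2]
  # translation update
  Kt <- Pt %*% solve(Pt + diag(3) * rn[1])
  tNew <- state@translation + as.numeric(Kt %*% (zt - state@translation))
  PtNew <- (diag(3) - Kt) %*% Pt
  # orientation update (multiplicative, rotation-vector error)
  q <- state@quaternion
  if (sum(zq * q) < 0) zq <- -zq
  dq <- quaternionMultiply(zq, quaternionConjugate(q))
  delta <- rotationMatrixToVector(quaternionToRotation(dq))
  Kq <- Pq %*% solve(Pq + diag(3) * rn[2])
  corr <- as.numeric(Kq %*% delta)
  qNew <- quaternionMultiply(rotationToQuaternion(rotationVectorToMatrix(corr)), q)
  qNew <- qNew / sqrt(sum(qNew^2))
  PqNew <- (diag(3) - Kq) %*% Pq
  for (P in list(PtNew, PqNew)) {
    ev <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-9)
      stopf(paste("pose filter covariance lost positive semi-definiteness;",
                  "reset the filter with poseFilter()"))
  }
  state@translation <- tNew
  state@Pt <- (PtNew + t(PtNew)) / 2
  state@quaternion <- qNew
  state@Pq <- (PqNew + t(PqNew)) / 2
  state
}

#' Current filtered pose
#'
#' @param state a [PoseFilterState-class] (must be initialised).
#' @param frameFrom,frameTo frame labels for the returned transform.
#' @return A [RigidTransform-class] with the filter's mean pose.
#' @export
filteredPose <- function(state, frameFrom = "MR", frameTo = "tracker") {
  if (!state@initialized) stopf("pose filter has not absorbed any measurement yet")
  rigidTransform(quaternionToRotation(state@quaternion), state@translation,
                 frameFrom, frameTo)
}
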