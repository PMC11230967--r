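---
title: "Markerless surface registration for tracked multimodal rigs: models and methods"
author: "SurfNav authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markerless surface registration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Image-guided neurosurgery needs the preoperative MR model of a patient's
head expressed in the coordinate system of the operating room. Conventional
workflows digitise fiducial landmarks with a tracked probe; SurfNav instead
registers the *surface* of the patient's face, captured by a depth camera,
against the same surface extracted from the MR volume — no markers on the
patient, no manual landmarking. Because the depth camera is itself a rigid
body tracked by an external optical system, the registration survives
camera motion: once the face has been registered, the rig can be moved to
the craniotomy, where a hyperspectral camera images the exposed tissue and
its frames can be painted onto the MR model.

Five rigid transforms (4x4 homogeneous matrices, millimetres; points are
column vectors, transforms act on the left) carry the whole geometry:

* `C` — tracker world <- camera rigid body, streamed by the tracker;
* `V` — tracker world <- IR optical frame, estimated by PnP during
  calibration;
* `M` — camera body <- IR optical frame, the fixed rig calibration,
  `M = C^-1 V`;
* `T` — MR <- IR optical frame, the per-frame surface registration;
* `G` — tracker world <- MR, the quantity everything else consumes,
  `G = C M T^-1`.

The package implements every stage: rig calibration (`calibrateTracking`),
inter-camera homographies (`estimateHomography`), depth-bias correction
(`fitDepthCorrection`), face extraction (`extractFaceCloud`), MR face
extraction (`extractMrFace`), registration (`ransacInitialTransform`,
`icpRefine`, `registerStream`), pose filtering (`kalmanUpdate`), error
metrics (`computeFre`, `computeTre`, `computeRre`) and a deterministic
phantom simulator (`simScene` and friends) standing in for all hardware.

## Camera model

Each camera is a zero-skew pinhole with the rational distortion model: six
radial coefficients forming the rational factor
`(1 + k1 r^2 + k2 r^4 + k3 r^6) / (1 + k4 r^2 + k5 r^4 + k6 r^6)` plus two
tangential terms. Pixels are `(u, v) = (column, row)` with the origin at
the top-left pixel centre; `+z` points into the scene, `+y` down. Depth
maps store z-depth, not ray length, matching RGBD sensor output.
Undistortion inverts the forward model by a damped fixed-point iteration
(damping 0.9, at most 50 iterations, tolerance 1e-8 in normalised
coordinates); the round-trip error is below 1e-4 px for realistic
coefficient magnitudes. Intrinsic calibration itself is out of scope:
intrinsics are inputs, produced by any standard calibration suite.

## Rig ("hand-eye" style) calibration

The tool is a bar of collinear flat reflective markers, tracked by the
optical system, photographed by the IR camera. Flat markers make the
tracked centre of mass coincide with the visual centre, so no cover-shift
correction is applied. Markers saturate the IR sensor; detection is a
threshold at 0.98 of the dynamic range followed by connected-component
labelling (minimum area 3 px). The centroid is then refined with intensity
weights over a window extending 12 px beyond each component, which uses
the unsaturated skirt of the blob for sub-pixel accuracy. Correspondences
follow the linear-tool convention: 3D markers sorted by descending
tracker-world x pair with image centroids sorted by ascending u. Ties
within tolerance raise an error rather than guess.

A single view of a collinear tool leaves the roll about the tool axis
undetermined, so per-capture pose estimation is rank-deficient by
construction. The default estimator therefore solves one *pooled* PnP
problem: every marker is mapped through its capture's `C^-1` into the
camera-body frame, where the constant pose `M^-1` is a single
perspective-n-point problem over all captures jointly — well-posed as soon
as the tool has been re-oriented between captures. A `method =
"per-capture"` path (PnP per capture, `M_i = C_i^-1 V_i`, consistency
check, chordal quaternion mean) is kept for tools with non-collinear
markers. PnP itself uses a DLT initialisation (for six or more well-spread
points) refined by Levenberg–Marquardt on the pixel reprojection error;
quality is reported as reprojection RMSE in pixels, pooled over all
markers per capture.

## Homography calibration

The RGB and hyperspectral cameras are related to the IR camera by planar
homographies estimated from chessboard-corner correspondences at a common
interpolated 4K resolution; native-resolution use goes through
`upscaleCorners`. Estimation is the normalised DLT (Hartley
preconditioning) with LM refinement that is kept only when it does not
worsen the residual; the quality figure is the RMS Euclidean reprojection
error over all pooled shots. A planar homography is only an approximation
between non-coplanar views of a 3D scene; it is accepted as such and the
RMSE records the cost.

## Depth-bias correction

Time-of-flight depth sensors carry a distance-dependent systematic error
of the order of a centimetre. The plane-sweep protocol measures a white
plane at 17 stations, 5 cm apart (250–1050 mm here), 25 repetitions each,
with the true distance from the tracker. `fitDepthCorrection` fits
corrected depth as a polynomial in raw depth — degree 2 by default, enough
for a smooth sensor bias without oscillation — on a centred basis for
conditioning, and refuses a non-monotone fit with the suggestion to lower
the degree. Standard errors come from the least-squares covariance, so
closed-loop tests can check coefficient recovery in units of standard
errors. The correction applies to z-depths, matching the protocol, which
measures along the optical axis.

## MR face extraction

From a NIfTI volume the head surface is extracted by marching tetrahedra
at an isosurface threshold (vertices on voxel edges by linear
interpolation, scanner-mm coordinates through the NIfTI affine, largest
connected component kept). The face then has to be presented to a virtual
camera the way the depth camera will see it:

* Principal component analysis of the surface points. The leading
  component is the long head axis (camera up); the second is the
  front–back axis. The second axis's *sign* — which way the nose points —
  is fixed by the skewness of the point projections: the nose is the
  dominant asymmetry of a face, giving the heavy positive tail. The first
  axis's sign is fixed the same way using the chin-ward asymmetry, and the
  third axis completes a right-handed frame. Near-isotropic surfaces
  (eigenvalue ratios below 1.05) raise an ambiguous-orientation error
  rather than return an arbitrary frame.
* Hidden point removal in the virtual camera frame: spherical flipping
  `p' = p + 2 (R - |p|) p / |p|` about the viewpoint with
  `R = radiusFactor * max |p|` (default factor 100), then the convex hull
  of the flipped set united with the viewpoint; hull vertices are the
  visible points. The default standoff of the virtual camera is 600 mm —
  the working distance of the simulated depth camera.

## Registration

The depth-derived face cloud (IR optical frame) is aligned to the MR face
cloud (virtual camera frame) in two stages.

*Global initialisation* (`ransacInitialTransform`): both clouds are voxel
downsampled (8 mm), surface normals estimated by local PCA (16
neighbours, oriented toward the camera), and fast point feature histograms
(33 bins) computed over a 40 mm radius. Nearest-descriptor matches feed a
RANSAC loop over match triplets with an edge-length compatibility gate;
hypotheses (Kabsch fits) are scored by inlier count at a 10 mm threshold
on a 300-point subsample, with adaptive termination at 0.999 confidence.
The winner is refit on all inliers. Everything is deterministic given the
seed.

*Refinement* (`icpRefine`): trimmed point-to-point ICP — nearest
neighbours, correspondences beyond a 25 mm cutoff dropped, Kabsch update,
stop when the relative change of the inlier RMSE falls below 1e-6 (1e-9
where closed-loop precision is wanted). The target may be a point cloud or
a triangle mesh; with a mesh, correspondences are closest points on the
surface, and a point-to-plane variant (Gauss–Newton on the normal
residuals) is available behind a flag. The mesh + point-to-plane
combination is what lets a noiseless closed loop converge to numerical
precision: a sampled point target floors the achievable error at its
sampling density, whereas the mesh carries the exact surface.

Per frame, `T` is re-expressed in the MR frame through the recorded PCA
alignment, and `G = C M T^-1`. In a stream, RANSAC runs on the first frame
only; later frames warm-start ICP from the previous `T`. The invariance
of `G` under camera motion — `C` and `T` change, their product does not —
is the property that makes the tracked rig useful, and is tested directly.

`G` measurements are smoothed by an error-state Kalman filter with a
constant-pose process model: linear update on the translation,
multiplicative update on the orientation via the rotation-vector error,
quaternion renormalised after each step. Defaults: process noise
0.1 mm^2 and 0.01 deg^2 per frame; measurement noise taken from the
per-frame ICP residuals for the translation and 0.5 deg^2 for the
orientation. The filter state is reset-able and refuses covariance
updates that lose positive semi-definiteness. Filtering `G` (not `T`) is
deliberate: `G` is the quantity meant to be stationary.

## Error metrics

* **FRE** — RMS nearest-neighbour distance from the registered face cloud
  to the MR face surface. RMS (not mean) follows the convention of the
  image-guided-surgery literature; the package's value is defined on
  exactly the points used in the registration.
* **TRE** — the evaluation cloud is captured at a position *not* used for
  registration, mapped into the MR frame through the registration-derived
  `G`, and residually aligned to the MR surface by ICP; the TRE is the RMS
  displacement of the evaluation points under that residual transform. A
  plain nearest-neighbour variant is available (`method = "nn"`).
* **RRE** — mean distance between MR landmarks mapped by two independent
  registrations of the same model.

All metrics are invariant under a common rigid transform of both
arguments. No ordering between FRE and TRE is asserted anywhere: TRE is
routinely larger.

## The phantom simulator

`simScene` assembles a fully synthetic acquisition: a parametric head
(ellipsoid cranium with semi-axes 70 x 100 x 80 mm, a 25 mm nose, brow and
chin asperities, and small seeded bumps so that different seeds give
different phantoms), a seeded head pose in tracker world, a 640 x 576 IR
camera at 600 mm standoff, and a ground-truth rig calibration `M`. Depth
frames are rasterised into a z-buffer with perspective-correct
interpolation, so noiseless depth pixels lie on the mesh to machine
precision — the property every closed-loop test rests on.

Noise defaults mirror the published characterisation of the emulated
hardware: a systematic depth bias `5 + 0.01 d` mm (11 mm at the 600 mm
working distance), tracker noise 0.34 mm RMS, marker-centroid noise
0.5 px. The single-pixel random depth error of such sensors is
characterised at up to ~17 mm standard deviation; the simulator's default
effective value is 2 mm, representing the spatial and temporal averaging
that any real consumer of the stream applies, with the worst case
available as a parameter for stress tests. Calibration markers are
rendered as Gaussian point-spread blobs whose core saturates smoothly
(`g (2 - g)` of a sigma = 2 px Gaussian): the profile is a polynomial in a
Gaussian, so its sampled intensity-weighted centroid equals the true
centre to numerical precision, and noiseless calibration recovery is
limited by the solver, not the renderer. Tool poses are rejection-sampled
until the linear-tool x/u ordering convention holds and blobs stay
separated, as an operator would naturally hold the tool.

What the simulator does *not* emulate: depth-dependent noise structure,
multipath and flying-pixel artefacts at silhouettes, specular dropout,
soft-tissue deformation, hair, or occlusions by drapes and instruments. A
passing closed loop therefore demonstrates the correctness of the
geometry and estimators, not robustness to clinical nuisance factors.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run, per scene: face clouds of
roughly 2,000–4,000 points after 4–5 mm downsampling against MR face
clouds of ~1,200 points (or the full ~6,000-triangle mesh), 20 calibration
captures of a 4-marker tool, 17 x 25 plane-sweep measurements, a 5 x 5
position grid with 5 evaluation trials (ICP capped at 60 iterations
there; the registration precision required by the error metrics is
reached long before), and 8-frame streams for the filter. These sizes were chosen so a full closed loop is a few seconds on
one core while estimator errors sit well below the tolerances being
checked. Ties and degeneracies error loudly rather than guess: collinear
PnP input, ambiguous marker ordering, isotropic PCA, non-monotone depth
fits, hulls of coincident points.

## Known limitations

* The RANSAC descriptors assume both clouds sample the surface at
  comparable density; matching a sparse mesh against a dense unprocessed
  depth frame degrades the inlier fraction (both inputs are voxel
  downsampled internally for this reason).
* The planar homography between non-coplanar cameras is an approximation;
  its RMSE is the honest quality figure.
* The Kalman filter's constant-pose model is right for a static patient;
  tracking a moving head would need a motion model and is out of scope.
* `detectMarkers`' windowed centroid assumes blobs are isolated within the
  refinement window; the merged-blob flag marks area outliers, and heavily
  overlapping markers are rejected upstream by the capture validity rules.
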