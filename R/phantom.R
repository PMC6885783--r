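#' Stylized anthropomorphic phantom
#'
#' A simplified MIRD-style stylized adult phantom built from geometric
#' primitives: an elliptic-cylinder trunk (70 cm tall, 40 x 20 cm section),
#' an elliptic-cylinder head and two cylindrical legs, with organs placed as
#' ellipsoids / elliptic cylinders at stylized positions and a 2 mm skin
#' shell over the body surface.  The body is homogeneous soft tissue
#' (density 1.04 g/cm^3); organs are tally regions, not separate materials.
#' Testes and genitalia are modelled inside the lower front trunk so that a
#' torso garment covers them, mirroring how vests shield the gonads.
#'
#' @param center_x,center_y Position of the body axis (cm); defaults centre
#'   the phantom in the 250 x 200 x 200 cm chamber.
#' @return Object of class `phantom`: list with `parts` (trunk/head/leg
#'   elliptic cylinders), `organs` matrix for the transport engine,
#'   `region_names`, `masses` (g), `areas` (skin areas per body part, cm^2)
#'   and `skin_thickness` (cm).
#' @export
stylized_phantom <- function(center_x = 125, center_y = 100) {
  rho <- 1.04
  # trunk, head, leg-left, leg-right: cx, cy, a, b, z0, z1
  parts <- rbind(
    trunk = c(0, 0, 20, 10, 80, 150),
    head  = c(0, 0, 7, 9, 150, 168),
    leg_l = c(-9.5, 0, 7.5, 7.5, 0, 80),
    leg_r = c(9.5, 0, 7.5, 7.5, 0, 80))
  parts[, 1] <- parts[, 1] + center_x
  parts[, 2] <- parts[, 2] + center_y
  colnames(parts) <- c("cx", "cy", "a", "b", "z0", "z1")

  # shape: 0 ellipsoid (cx,cy,cz,ax,ay,az), 1 elliptic z-cylinder
  # (cx,cy,ax,ay,z0,z1); region ids are 0-based for the engine
  og <- function(shape, cx, cy, cz, ax, ay, az, z0, z1, region)
    c(shape, cx + center_x, cy + center_y, cz, ax, ay, az, z0, z1, region)
  organs <- rbind(
    og(0, -9.5, 1, 128, 4.5, 6.5, 10, 0, 0, 0),    # lung left
    og(0,  9.5, 1, 128, 4.5, 6.5, 10, 0, 0, 0),    # lung right
    og(0, -6, -3, 112, 4, 3, 5.5, 0, 0, 1),        # stomach
    og(1, -10.5, -1, 0, 2.2, 2.2, 0, 88, 102, 2),  # colon desc.
    og(1,  10.5, -1, 0, 2.2, 2.2, 0, 88, 102, 2),  # colon asc.
    og(0, 0, -8, 81.5, 2.8, 1.5, 1.5, 0, 0, 3),    # testes + genitalia
    og(0, 7, -2, 108, 8, 6, 5, 0, 0, 4),           # liver
    og(1, 0, 2.5, 0, 0.8, 0.8, 0, 125, 148, 5),    # oesophagus
    og(0, 0, -4, 84, 3.5, 3, 2.5, 0, 0, 6),        # urinary bladder
    og(0, 0, -1.5, 94, 8, 4.5, 5, 0, 0, 7),        # small intestine
    og(0, 4, -6, 104, 2, 1.5, 3, 0, 0, 8),         # gall bladder
    og(0, -4, 1.5, 105, 5, 1.8, 2, 0, 0, 9),       # pancreas
    og(0, -9.5, 3, 108, 3, 2.5, 4, 0, 0, 10),      # spleen
    og(0, 0, -3, 123, 5, 4, 4.5, 0, 0, 11),        # heart
    og(0, -5.5, 5.5, 109, 1.5, 1, 1.2, 0, 0, 12),  # adrenal left
    og(0,  5.5, 5.5, 109, 1.5, 1, 1.2, 0, 0, 12),  # adrenal right
    og(0, -5.5, 5.5, 103, 2.5, 2, 4.5, 0, 0, 13),  # kidney left
    og(0,  5.5, 5.5, 103, 2.5, 2, 4.5, 0, 0, 13),  # kidney right
    og(0, 0, -4.5, 138, 2.5, 1.2, 2, 0, 0, 14),    # thymus
    og(0, 0, 0, 161, 6, 7.5, 5.5, 0, 0, 15),       # brain
    og(0, 0, -3.5, 152, 2, 1.2, 2, 0, 0, 16))      # thyroid
  colnames(organs) <- c("shape", "cx", "cy", "cz", "ax", "ay", "az",
                        "z0", "z1", "region")

  organ_names <- c("lungs", "stomach", "colon", "testes", "liver",
                   "oesophagus", "bladder", "small_intestine",
                   "gall_bladder", "pancreas", "spleen", "heart",
                   "adrenals", "kidneys", "thymus", "brain", "thyroid")
  region_names <- c(organ_names, "skin", "other_trunk", "other_legs",
                    "other_head", "garment", "air", "wall")

  vol1 <- function(r) {
    if (r["shape"] == 0) 4 / 3 * pi * r["ax"] * r["ay"] * r["az"]
    else pi * r["ax"] * r["ay"] * (r["z1"] - r["z0"])
  }
  ov <- apply(organs, 1, vol1)
  organ_vol <- tapply(ov, factor(organs[, "region"], levels = 0:16), sum)

  # skin areas from the lateral surfaces (+ head top, leg bottoms)
  per_ell <- function(a, b) pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  a_trunk <- per_ell(20, 10) * 70
  a_head <- per_ell(7, 9) * 18 + pi * 7 * 9
  a_legs <- 2 * (2 * pi * 7.5 * 80 + pi * 7.5^2)
  skin_t <- 0.2
  v_skin <- (a_trunk + a_head + a_legs) * skin_t

  v_trunk <- pi * 20 * 10 * 70
  v_head <- pi * 7 * 9 * 18
  v_legs <- 2 * pi * 7.5^2 * 80
  org_in_head <- sum(organ_vol[16:17])
  org_in_trunk <- sum(organ_vol) - org_in_head
  vols <- c(organ_vol,
            skin = v_skin,
            other_trunk = v_trunk - org_in_trunk - a_trunk * skin_t,
            other_legs = v_legs - a_legs * skin_t,
            other_head = v_head - org_in_head - a_head * skin_t)
  masses <- setNames(as.numeric(vols) * rho,
                     c(organ_names, "skin", "other_trunk", "other_legs",
                       "other_head"))

  structure(list(parts = parts, organs = organs,
                 region_names = region_names,
                 organ_names = organ_names,
                 masses = masses,
                 areas = c(trunk = a_trunk, head = a_head, legs = a_legs),
                 skin_thickness = skin_t,
                 rho_tissue = rho,
                 n_organ_regions = length(organ_names)),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> stylized adult,", length(x$organ_names), "organ regions,",
      sprintf("total mass %.1f kg\n", sum(x$masses) / 1000))
  invisible(x)
}
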