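# Percentage footprint coordinates of the ACL bundle centres, expressed as
# fractions of the quadrant-grid extents.
#   femur:  [height fraction from the superior border,
#            depth fraction from the posterior border]
#   tibia:  [depth fraction from the anterior border,
#            width fraction from the medial border]
# The central bundle point is derived as the re-projected midpoint of AM
# and PL and therefore has no independent entry.
version: 1
femur:
  AM: [0.250, 0.330]
  PL: [0.451, 0.500]
tibia:
  AM: [0.350, 0.505]
  PL: [0.464, 0.524]
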