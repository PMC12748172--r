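# Caption templates for vessel text labels. Each caption is assembled from
# one density sentence, one distribution sentence, and one clause per
# abnormal area. Users may supply their own file with the same keys.
density:
  sparse: "Vessel density is low, with only a few vessels visible against the background."
  moderate: "Vessel density is moderate, with vessels covering part of the image."
  dense: "Vessel density is high, with vessels covering much of the image."
distribution:
  radial: "The vessels radiate from the periphery to the center in a root-like pattern, gradually thinning toward the center, leaving the middle of the image free of vessels."
  reticular: "The vessels form a fine reticular mesh spread across the image, sparing the central avascular zone."
  mixed: "The vessels show a mixed pattern, with both radial trunks and reticular fine branches."
abnormal: "An abnormal area is present in the {region} region."
abnormal_none: ""
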