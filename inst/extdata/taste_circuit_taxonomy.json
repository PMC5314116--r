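{
  "regions": [
    {
      "label": "anterior_cingulate",
      "hemisphere": "left",
      "volume": 640
    },
    {
      "label": "basolateral_amygdala",
      "hemisphere": "left",
      "volume": 140
    },
    {
      "label": "central_nucleus_amygdala",
      "hemisphere": "left",
      "volume": 60
    },
    {
      "label": "dorsal_anterior_insula",
      "hemisphere": "left",
      "volume": 320
    },
    {
      "label": "frontal_operculum",
      "hemisphere": "left",
      "volume": 350
    },
    {
      "label": "gyrus_rectus",
      "hemisphere": "left",
      "volume": 260
    },
    {
      "label": "hypothalamus",
      "hemisphere": "left",
      "volume": 80
    },
    {
      "label": "inferior_OFC",
      "hemisphere": "left",
      "volume": 340
    },
    {
      "label": "medial_OFC",
      "hemisphere": "left",
      "volume": 380
    },
    {
      "label": "medial_PFC",
      "hemisphere": "left",
      "volume": 520
    },
    {
      "label": "middle_OFC",
      "hemisphere": "left",
      "volume": 420
    },
    {
      "label": "posterior_insula",
      "hemisphere": "left",
      "volume": 410
    },
    {
      "label": "substantia_nigra",
      "hemisphere": "left",
      "volume": 90
    },
    {
      "label": "thalamus",
      "hemisphere": "left",
      "volume": 1050
    },
    {
      "label": "ventral_anterior_insula",
      "hemisphere": "left",
      "volume": 280
    },
    {
      "label": "ventral_striatum",
      "hemisphere": "left",
      "volume": 220
    },
    {
      "label": "anterior_cingulate",
      "hemisphere": "right",
      "volume": 640
    },
    {
      "label": "basolateral_amygdala",
      "hemisphere": "right",
      "volume": 140
    },
    {
      "label": "central_nucleus_amygdala",
      "hemisphere": "right",
      "volume": 60
    },
    {
      "label": "dorsal_anterior_insula",
      "hemisphere": "right",
      "volume": 320
    },
    {
      "label": "frontal_operculum",
      "hemisphere": "right",
      "volume": 350
    },
    {
      "label": "gyrus_rectus",
      "hemisphere": "right",
      "volume": 260
    },
    {
      "label": "hypothalamus",
      "hemisphere": "right",
      "volume": 80
    },
    {
      "label": "inferior_OFC",
      "hemisphere": "right",
      "volume": 340
    },
    {
      "label": "medial_OFC",
      "hemisphere": "right",
      "volume": 380
    },
    {
      "label": "medial_PFC",
      "hemisphere": "right",
      "volume": 520
    },
    {
      "label": "middle_OFC",
      "hemisphere": "right",
      "volume": 420
    },
    {
      "label": "posterior_insula",
      "hemisphere": "right",
      "volume": 410
    },
    {
      "label": "substantia_nigra",
      "hemisphere": "right",
      "volume": 90
    },
    {
      "label": "thalamus",
      "hemisphere": "right",
      "volume": 1050
    },
    {
      "label": "ventral_anterior_insula",
      "hemisphere": "right",
      "volume": 280
    },
    {
      "label": "ventral_striatum",
      "hemisphere": "right",
      "volume": 220
    }
  ],
  "pairs": {
    "thalamus": ["dorsal_anterior_insula", "ventral_anterior_insula", "posterior_insula", "frontal_operculum"],
    "dorsal_anterior_insula": ["basolateral_amygdala", "central_nucleus_amygdala", "ventral_striatum", "medial_PFC", "medial_OFC", "middle_OFC", "gyrus_rectus", "inferior_OFC"],
    "ventral_anterior_insula": ["basolateral_amygdala", "central_nucleus_amygdala", "ventral_striatum", "medial_PFC", "medial_OFC", "middle_OFC", "gyrus_rectus", "inferior_OFC"],
    "posterior_insula": ["basolateral_amygdala", "central_nucleus_amygdala", "ventral_striatum", "medial_PFC", "medial_OFC", "middle_OFC", "gyrus_rectus", "inferior_OFC"],
    "substantia_nigra": ["ventral_striatum"],
    "central_nucleus_amygdala": ["hypothalamus", "substantia_nigra", "ventral_striatum", "anterior_cingulate"],
    "basolateral_amygdala": ["hypothalamus", "substantia_nigra", "ventral_striatum", "anterior_cingulate"],
    "medial_OFC": ["hypothalamus", "ventral_striatum", "medial_PFC"],
    "middle_OFC": ["hypothalamus", "ventral_striatum", "medial_PFC"],
    "gyrus_rectus": ["hypothalamus", "ventral_striatum", "medial_PFC"],
    "inferior_OFC": ["hypothalamus", "ventral_striatum", "medial_PFC"]
  }
}
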