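{
  "reference_id": "syn01",
  "scrs": [
    {
      "name": "SCR1",
      "start_col": 9,
      "end_col": 14,
      "content": ""
    },
    {
      "name": "SCR2",
      "start_col": 23,
      "end_col": 32,
      "content": ""
    },
    {
      "name": "SCR3",
      "start_col": 41,
      "end_col": 46,
      "content": ""
    },
    {
      "name": "SCR4",
      "start_col": 74,
      "end_col": 87,
      "content": ""
    },
    {
      "name": "SCR5",
      "start_col": 96,
      "end_col": 104,
      "content": ""
    },
    {
      "name": "SCR6",
      "start_col": 113,
      "end_col": 119,
      "content": ""
    },
    {
      "name": "SCR7",
      "start_col": 128,
      "end_col": 133,
      "content": ""
    },
    {
      "name": "SCR8",
      "start_col": 142,
      "end_col": 154,
      "content": ""
    },
    {
      "name": "SCR9",
      "start_col": 163,
      "end_col": 174,
      "content": ""
    },
    {
      "name": "SCR10",
      "start_col": 183,
      "end_col": 191,
      "content": ""
    },
    {
      "name": "SCR11",
      "start_col": 200,
      "end_col": 213,
      "content": ""
    },
    {
      "name": "SCR12",
      "start_col": 236,
      "end_col": 245,
      "content": ""
    },
    {
      "name": "SCR13",
      "start_col": 254,
      "end_col": 262,
      "content": ""
    },
    {
      "name": "SCR14",
      "start_col": 271,
      "end_col": 277,
      "content": ""
    },
    {
      "name": "SCR15",
      "start_col": 286,
      "end_col": 293,
      "content": ""
    },
    {
      "name": "SCR16",
      "start_col": 317,
      "end_col": 330,
      "content": ""
    },
    {
      "name": "SCR17",
      "start_col": 339,
      "end_col": 352,
      "content": ""
    },
    {
      "name": "SCR18",
      "start_col": 361,
      "end_col": 369,
      "content": ""
    },
    {
      "name": "SCR19",
      "start_col": 378,
      "end_col": 387,
      "content": ""
    }
  ],
  "anchors": {
    "f87_col": 60,
    "glu_col": 271,
    "arg_col": 274,
    "cys_col": 324
  },
  "ris1": {
    "left_col": 213,
    "right_col": 236
  },
  "ris2": {
    "left_col": 293,
    "right_col": 317
  },
  "class_labels": {
    "syn01": "classII",
    "syn02": "classI",
    "syn03": "classII_verylongRIS2",
    "syn04": "classII",
    "syn05": "classII",
    "syn06": "classII",
    "syn07": "classII_verylongRIS2",
    "syn08": "classI",
    "syn09": "classI",
    "syn10": "classI",
    "syn11": "classI",
    "syn12": "classII",
    "syn13": "classI",
    "syn14": "classII",
    "syn15": "classII_verylongRIS2",
    "syn16": "classI",
    "syn17": "classI",
    "syn18": "classI",
    "syn19": "classII",
    "syn20": "classII"
  }
}
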