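accession_id,name,collection,country,clonal_type
ACC-01,Blue Congo,NordGen,Sweden,landrace
ACC-02,Svartpotet,NGS,Norway,landrace
ACC-03,Early Morn,LKF-Vandel,Denmark,improved variety
ACC-04,Jamtlands Vit,NordGen,Sweden,landrace
ACC-05,Mandel klon 1,NGS,Norway,landrace
ACC-06,Mandel klon 2,NGS,Norway,landrace
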