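code_system,code,phenotype_tag,description
ICD10,I21,MI,Acute myocardial infarction
ICD10,I22,MI,Subsequent myocardial infarction
ICD10,I23,MI,Complications following acute myocardial infarction
ICD10,I241,MI,Dressler syndrome
ICD10,I252,MI,Old myocardial infarction
ICD9,410,MI,Acute myocardial infarction
ICD9,412,MI,Old myocardial infarction
ICD10,I20,CAD_noMI,Angina pectoris
ICD10,I240,CAD_noMI,Coronary thrombosis not resulting in myocardial infarction
ICD10,I248,CAD_noMI,Other forms of acute ischaemic heart disease
ICD10,I249,CAD_noMI,Acute ischaemic heart disease unspecified
ICD10,I25,CAD_noMI,Chronic ischaemic heart disease (I252 excluded via longest prefix)
OPCS4,K40,CAD_noMI,Saphenous vein graft replacement of coronary artery
OPCS4,K41,CAD_noMI,Other autograft replacement of coronary artery
OPCS4,K42,CAD_noMI,Allograft replacement of coronary artery
OPCS4,K43,CAD_noMI,Prosthetic replacement of coronary artery
OPCS4,K44,CAD_noMI,Other replacement of coronary artery
OPCS4,K45,CAD_noMI,Connection of thoracic artery to coronary artery
OPCS4,K46,CAD_noMI,Other bypass of coronary artery
OPCS4,K49,CAD_noMI,Transluminal balloon angioplasty of coronary artery
OPCS4,K50,CAD_noMI,Other therapeutic transluminal operations on coronary artery
OPCS4,K75,CAD_noMI,Percutaneous transluminal balloon angioplasty and stenting of coronary artery
SELFREPORT,CABG,CAD_noMI,Self-reported coronary artery bypass graft
SELFREPORT,PTCA,CAD_noMI,Self-reported percutaneous coronary angioplasty
SELFREPORT,ANGIOPLASTY,CAD_noMI,Self-reported coronary angioplasty
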