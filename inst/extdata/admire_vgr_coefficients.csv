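comparison,criterion,label,algorithm,a,b,b_significant
IR_vs_FBP,1,Liver parenchyma,IR3,2.28,0.57,TRUE
IR_vs_FBP,1,Liver parenchyma,IR5,2.28,-0.08,FALSE
IR_vs_FBP,2,Pancreatic contours,IR3,2.00,0.92,TRUE
IR_vs_FBP,2,Pancreatic contours,IR5,2.00,1.73,TRUE
IR_vs_FBP,3,Kidneys and proximal ureters,IR3,2.21,1.11,TRUE
IR_vs_FBP,3,Kidneys and proximal ureters,IR5,2.21,2.09,TRUE
IR_vs_FBP,4,Lymph nodes < 15 mm,IR3,1.72,1.05,TRUE
IR_vs_FBP,4,Lymph nodes < 15 mm,IR5,1.72,1.93,TRUE
IR_vs_FBP,5,Image noise,IR3,2.38,1.50,TRUE
IR_vs_FBP,5,Image noise,IR5,2.38,3.16,TRUE
IR_vs_FBP,6,Overall image quality,IR3,2.69,1.06,TRUE
IR_vs_FBP,6,Overall image quality,IR5,2.69,1.10,TRUE
IR5_vs_IR3,1,Liver parenchyma,IR5,1.88,-0.98,TRUE
IR5_vs_IR3,2,Pancreatic contours,IR5,1.84,0.61,TRUE
IR5_vs_IR3,3,Kidneys and proximal ureters,IR5,2.06,0.77,TRUE
IR5_vs_IR3,4,Lymph nodes < 15 mm,IR5,1.49,0.68,TRUE
IR5_vs_IR3,5,Image noise,IR5,2.42,1.66,TRUE
IR5_vs_IR3,6,Overall image quality,IR5,3.18,-0.85,FALSE
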