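sign,comparison,reviewer,n_pos,n_neg,sensitivity,specificity,ppv,npv,accuracy
mcp_hyper,MSAvsSCA3,1,32,8,90.6,75.0,93.5,66.7,87.5
mcp_hyper,MSAvsSCA3,2,32,8,96.9,12.5,81.6,50.0,80.0
mcp_hyper,MSAvsSCA3,3,32,8,84.4,87.5,96.4,58.3,85.0
mcp_hyper,MSAvsSCA6,1,32,16,90.6,100,100,84.2,93.8
mcp_hyper,MSAvsSCA6,2,32,16,96.9,100,100,94.1,97.9
mcp_hyper,MSAvsSCA6,3,32,16,84.4,100,100,76.2,89.6
mcp_hyper,SCA3vsSCA6,1,8,16,25.0,100,100,72.7,75.0
mcp_hyper,SCA3vsSCA6,2,8,16,87.5,100,100,94.1,95.8
mcp_hyper,SCA3vsSCA6,3,8,16,12.5,100,100,69.6,70.8
hcb_grade2,MSAvsSCA3,1,32,8,59.4,100,100,38.1,67.5
hcb_grade2,MSAvsSCA3,2,32,8,81.2,100,100,57.1,85.0
hcb_grade2,MSAvsSCA3,3,32,8,75.0,87.5,96.0,46.7,77.5
hcb_grade2,MSAvsSCA6,1,32,16,59.4,100,100,55.2,72.9
hcb_grade2,MSAvsSCA6,2,32,16,81.2,100,100,72.7,87.5
hcb_grade2,MSAvsSCA6,3,32,16,75.0,100,100,66.7,83.3
hcb_grade2,SCA3vsSCA6,1,8,16,0,100,NA,66.7,66.7
hcb_grade2,SCA3vsSCA6,2,8,16,0,100,NA,66.7,66.7
hcb_grade2,SCA3vsSCA6,3,8,16,12.5,100,100,69.6,70.8
hcb_grade12,MSAvsSCA3,1,32,8,87.5,12.5,80.0,20.0,72.5
hcb_grade12,MSAvsSCA3,2,32,8,93.8,0,78.9,0,75.0
hcb_grade12,MSAvsSCA3,3,32,8,100,0,80.0,NA,80.0
hcb_grade12,MSAvsSCA6,1,32,16,87.5,93.8,96.6,78.9,89.6
hcb_grade12,MSAvsSCA6,2,32,16,93.8,93.8,96.8,88.2,93.8
hcb_grade12,MSAvsSCA6,3,32,16,100,31.2,74.4,100,77.1
hcb_grade12,SCA3vsSCA6,1,8,16,87.5,93.8,87.5,93.8,91.7
hcb_grade12,SCA3vsSCA6,2,8,16,100,93.8,88.9,100,95.8
hcb_grade12,SCA3vsSCA6,3,8,16,100,31.2,42.1,100,54.2
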